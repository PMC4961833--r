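# Readers/writers for the external formats: OBO flat-file subset, thesaurus
# TSVs, association tables, gene feature tables, the source manifest.

#' Read a disease ontology from an OBO flat file (subset)
#'
#' Parses `[Term]` stanzas and the tags `id`, `name`, `synonym` (the quoted
#' string), `xref`, `is_a`. Terms marked `is_obsolete: true` are dropped;
#' unknown tags are skipped. Parent links must be acyclic.
#'
#' @param path OBO file.
#' @return a `disease_ontology`: named list of terms, each a list with
#'   `term_id`, `name`, `synonyms`, `xrefs`, `parents`.
#' @export
read_obo <- function(path) {
  if (!file.exists(path)) stop_arg("no such file: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  terms <- list()
  cur <- NULL
  in_term <- FALSE
  flush <- function(cur) {
    if (is.null(cur) || isTRUE(cur$obsolete)) return(invisible())
    if (is.null(cur$term_id) || is.null(cur$name)) {
      stop_arg("malformed [Term] stanza ending near line ", cur$line,
               ": id and name are required")
    }
    if (cur$term_id %in% names(terms)) {
      stop_arg("duplicate term id: ", cur$term_id)
    }
    terms[[cur$term_id]] <<- list(term_id = cur$term_id, name = cur$name,
                                  synonyms = cur$synonyms, xrefs = cur$xrefs,
                                  parents = cur$parents)
  }
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (ln == "[Term]") {
      flush(cur)
      cur <- list(term_id = NULL, name = NULL, synonyms = character(0),
                  xrefs = character(0), parents = character(0),
                  obsolete = FALSE, line = i)
      in_term <- TRUE
      next
    }
    if (grepl("^\\[", ln)) { # other stanza type ([Typedef], ...)
      flush(cur); cur <- NULL; in_term <- FALSE
      next
    }
    if (!in_term || !nzchar(ln) || startsWith(ln, "!")) next
    if (!grepl("^[A-Za-z_]+:", ln)) {
      stop_arg("malformed OBO line ", i, ": ", ln)
    }
    tag <- sub(":.*$", "", ln)
    val <- trimws(sub("^[A-Za-z_]+:", "", ln))
    val <- trimws(sub("!.*$", "", val)) # trailing comments
    if (tag == "id") cur$term_id <- val
    else if (tag == "name") cur$name <- val
    else if (tag == "synonym") {
      m <- regmatches(val, regexec('^"([^"]*)"', val))[[1]]
      if (length(m) < 2L) stop_arg("malformed synonym at line ", i, ": ", ln)
      cur$synonyms <- c(cur$synonyms, m[2])
    }
    else if (tag == "xref") cur$xrefs <- c(cur$xrefs, sub("\\s.*$", "", val))
    else if (tag == "is_a") cur$parents <- c(cur$parents,
                                             sub("\\s.*$", "", val))
    else if (tag == "is_obsolete" && val == "true") cur$obsolete <- TRUE
    # any other tag: skipped
  }
  flush(cur)
  onto <- structure(terms, class = "disease_ontology")
  check_acyclic(onto)
  onto
}

check_acyclic <- function(ontology) {
  state <- new.env(parent = emptyenv())
  visit <- function(id, stack) {
    if (id %in% stack) stop_arg("is_a cycle involving term ", id)
    if (isTRUE(state[[id]])) return(invisible())
    for (p in ontology[[id]]$parents) {
      if (p %in% names(ontology)) visit(p, c(stack, id))
    }
    state[[id]] <- TRUE
  }
  for (id in names(ontology)) visit(id, character(0))
  invisible(ontology)
}

#' @export
print.disease_ontology <- function(x, ...) {
  cat("Disease ontology:", length(x), "terms,",
      sum(lengths(lapply(x, `[[`, "parents"))), "is-a links\n")
  invisible(x)
}

#' Write a disease ontology as an OBO flat file (subset)
#'
#' Inverse of [read_obo()] over the supported tags; round-trips semantically.
#'
#' @param ontology a `disease_ontology`.
#' @param path output file.
#' @export
write_obo <- function(ontology, path) {
  stopifnot(inherits(ontology, "disease_ontology"))
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("format-version: 1.2", con)
  for (t in ontology) {
    writeLines(c("", "[Term]",
                 paste0("id: ", t$term_id),
                 paste0("name: ", t$name),
                 if (length(t$synonyms))
                   paste0("synonym: \"", t$synonyms, "\" EXACT []"),
                 if (length(t$xrefs)) paste0("xref: ", t$xrefs),
                 if (length(t$parents)) paste0("is_a: ", t$parents)), con)
  }
  invisible(path)
}

#' Read a supplementary thesaurus (code \\t name TSV)
#'
#' @param path TSV with two columns `code`, `name` (header optional).
#' @return data.frame with columns `code`, `name`.
#' @export
read_thesaurus <- function(path) {
  if (!file.exists(path)) stop_arg("no such file: ", path)
  df <- utils::read.delim(path, header = FALSE, colClasses = "character",
                          quote = "", comment.char = "")
  if (ncol(df) != 2L) stop_arg("thesaurus file must have 2 columns: ", path)
  names(df) <- c("code", "name")
  if (identical(tolower(df$code[1]), "code")) df <- df[-1L, , drop = FALSE]
  df$code <- trimws(df$code); df$name <- trimws(df$name)
  rownames(df) <- NULL
  df
}

#' Read gene-disease association records
#'
#' Three tab-separated columns: disease name, disease class, gene symbol
#' (header optional). Rows with a blank disease or gene are dropped; the
#' count of dropped rows is attached as attribute `n_dropped`.
#'
#' @param path TSV file.
#' @return data.frame with columns `disease_name`, `disease_class`,
#'   `gene_symbol`.
#' @export
read_associations <- function(path) {
  if (!file.exists(path)) stop_arg("no such file: ", path)
  raw <- readLines(path, warn = FALSE, encoding = "UTF-8")
  raw <- raw[nzchar(trimws(raw))]
  if (!length(raw)) {
    out <- data.frame(disease_name = character(0),
                      disease_class = character(0),
                      gene_symbol = character(0), stringsAsFactors = FALSE)
    attr(out, "n_dropped") <- 0L
    return(out)
  }
  n_tab <- lengths(regmatches(raw, gregexpr("\t", raw, fixed = TRUE)))
  bad <- which(n_tab != 2L)
  if (length(bad)) {
    stop_arg("association row ", bad[1], " has ", n_tab[bad[1]] + 1L,
             " columns, expected 3")
  }
  parts <- lapply(strsplit(raw, "\t", fixed = TRUE), function(p) {
    length(p) <- 3L            # trailing blank fields survive as ""
    ifelse(is.na(p), "", p)
  })
  df <- data.frame(do.call(rbind, parts), stringsAsFactors = FALSE)
  names(df) <- c("disease_name", "disease_class", "gene_symbol")
  df[] <- lapply(df, trimws)
  if (tolower(df$disease_name[1]) %in% c("disease", "disease_name")) {
    df <- df[-1L, , drop = FALSE]
  }
  keep <- nzchar(df$disease_name) & nzchar(df$gene_symbol)
  n_dropped <- sum(!keep)
  df <- df[keep, , drop = FALSE]
  df$gene_symbol <- toupper(df$gene_symbol)
  rownames(df) <- NULL
  attr(df, "n_dropped") <- n_dropped
  df
}

#' Read gene feature tables listed in a manifest
#'
#' Each source is a TSV `gene_symbol \t feature1;feature2;...`. One feature
#' vector is built per gene appearing in any source; missing (gene, source)
#' pairs become empty sets. A gene symbol appearing twice within one source
#' is an error (ambiguous features).
#'
#' @param manifest a manifest list from [read_manifest()], or a named
#'   character vector of source paths (names = source names).
#' @return a [gene_features()] collection.
#' @export
read_gene_features <- function(manifest) {
  if (is.character(manifest)) {
    src <- data.frame(name = names(manifest) %||%
                        paste0("source", seq_along(manifest)),
                      path = unname(manifest), stringsAsFactors = FALSE)
  } else {
    src <- manifest$sources
  }
  per_source <- lapply(seq_len(nrow(src)), function(i) {
    p <- src$path[i]
    if (!file.exists(p)) stop_arg("no such source file: ", p)
    raw <- readLines(p, warn = FALSE, encoding = "UTF-8")
    raw <- raw[nzchar(trimws(raw))]
    if (!length(raw)) return(list())
    parts <- strsplit(raw, "\t", fixed = TRUE)
    syms <- toupper(trimws(vapply(parts, `[[`, "", 1L)))
    if (anyDuplicated(syms)) {
      stop_arg("duplicate gene row for ",
               syms[duplicated(syms)][1], " in source ", src$name[i])
    }
    feats <- lapply(parts, function(pp) {
      if (length(pp) < 2L) return(character(0))
      toks <- strsplit(pp[[2L]], ";", fixed = TRUE)[[1]]
      toks <- norm_token(toks)
      unique(toks[nzchar(toks)])
    })
    names(feats) <- syms
    feats
  })
  all_genes <- sort(unique(unlist(lapply(per_source, names))))
  vectors <- lapply(all_genes, function(g) {
    lapply(per_source, function(s) s[[g]] %||% character(0))
  })
  names(vectors) <- all_genes
  gene_features(vectors, sources = src$name)
}

#' Read a source manifest (YAML or JSON)
#'
#' The manifest lists the gene feature sources (with optional per-source
#' weights), the ontology, thesauri, the association table, and the pipeline
#' parameters `threshold`, `ambiguous_floor`, `seed`.
#'
#' @param path YAML (or JSON) manifest file.
#' @return a list with elements `sources` (data.frame `name`, `path`,
#'   `alpha`), `ontology_path`, `thesaurus_paths` (named), `association_path`,
#'   `threshold`, `ambiguous_floor`, `seed`.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop_arg("no such file: ", path)
  m <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    ifelse(file.exists(p) | grepl("^/", p), p, file.path(base, p))
  }
  src <- do.call(rbind, lapply(m$sources, function(s) {
    data.frame(name = s$name, path = resolve(s$path),
               alpha = if (is.null(s$alpha)) NA_real_ else as.numeric(s$alpha),
               stringsAsFactors = FALSE)
  }))
  if (all(is.na(src$alpha))) {
    src$alpha <- 1 / nrow(src)
  } else if (anyNA(src$alpha)) {
    stop_arg("either all sources or none must declare alpha")
  } else if (abs(sum(src$alpha) - 1) > 1e-9) {
    stop_arg("declared alpha weights must sum to 1")
  }
  th <- m$thesauri %||% list()
  th_paths <- vapply(th, function(t) resolve(t$path), "")
  names(th_paths) <- vapply(th, `[[`, "", "name")
  list(
    sources = src,
    ontology_path = if (!is.null(m$ontology)) resolve(m$ontology) else NULL,
    thesaurus_paths = th_paths,
    association_path = if (!is.null(m$associations))
      resolve(m$associations) else NULL,
    threshold = as.numeric(m$threshold %||% 0),
    ambiguous_floor = as.numeric(m$ambiguous_floor %||% 0.2),
    seed = as.integer(m$seed %||% 1L)
  )
}

#' Load the thesauri named in a manifest
#'
#' @param manifest list from [read_manifest()].
#' @return named list of thesaurus data.frames (see [read_thesaurus()]).
#' @export
read_thesauri <- function(manifest) {
  lapply(manifest$thesaurus_paths, read_thesaurus)
}
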