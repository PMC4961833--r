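# Seeded synthetic fixture bundles: toy gene feature tables, a toy disease
# ontology with synonyms/xrefs, a thesaurus, and an association table with
# planted structure, plus a truth file holding the generator's own
# closed-form expectations. Everything downstream is testable offline.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Specify a synthetic fixture bundle
#'
#' @param n_genes total genes (>= 12; the first few are reserved for planted
#'   similarity regimes and planted paths).
#' @param n_sources feature sources (>= 2).
#' @param n_terms ontology terms beyond the planted ones (>= 0).
#' @param n_associations association rows beyond the planted ones (>= 0).
#' @param planted_path_lengths integer vector; one disease-gene path of each
#'   requested length (1 to 4 supported by construction) is planted with a
#'   closed-form expected confidence.
#' @param feature_overlap_level fraction of tokens shared by the planted
#'   partial-overlap gene pair and by planted gene-gene path edges; must
#'   exceed 0.5 so the planted edges survive the default threshold 0.
#' @param seed integer seed; bundles are bit-reproducible per seed.
#' @return a `fixture_spec` list.
#' @export
fixture_spec <- function(n_genes = 30, n_sources = 3, n_terms = 12,
                         n_associations = 15,
                         planted_path_lengths = c(1L, 2L, 3L),
                         feature_overlap_level = 0.8, seed = 1L) {
  if (n_genes < 12) stop_arg("n_genes must be >= 12")
  if (n_sources < 2) stop_arg("n_sources must be >= 2")
  if (n_terms < 0 || n_associations < 0) stop_arg("counts must be positive")
  if (any(planted_path_lengths < 1)) stop_arg("planted path lengths >= 1")
  if (any(planted_path_lengths > 4)) {
    stop_arg("cannot plant a path longer than 4 edges in this graph family")
  }
  if (feature_overlap_level <= 0.5 || feature_overlap_level > 1) {
    stop_arg("feature_overlap_level must be in (0.5, 1]")
  }
  structure(list(n_genes = n_genes, n_sources = n_sources, n_terms = n_terms,
                 n_associations = n_associations,
                 planted_path_lengths = as.integer(planted_path_lengths),
                 feature_overlap_level = feature_overlap_level,
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

# token sets for a pair with a planted sharing fraction, per source;
# returns list(a = , b = , similarity = exact value)
planted_pair_tokens <- function(tag, n_sources, level) {
  total <- 10L
  shared <- max(6L, min(total, round(level * total)))
  private <- max(1L, round((total - shared) / 2))
  a <- b <- vector("list", n_sources)
  for (m in seq_len(n_sources)) {
    c_tok <- sprintf("%s.s%d.c%02d", tag, m, seq_len(shared))
    a[[m]] <- c(c_tok, sprintf("%s.s%d.a%02d", tag, m, seq_len(private)))
    b[[m]] <- c(c_tok, sprintf("%s.s%d.b%02d", tag, m, seq_len(private)))
  }
  sim <- mean(vapply(seq_len(n_sources), function(m)
    source_overlap_score(a[[m]], b[[m]]), numeric(1)))
  list(a = a, b = b, similarity = sim)
}

#' Generate a synthetic fixture bundle on disk
#'
#' Writes one feature TSV per source, an OBO ontology, a synthetic thesaurus
#' (MESH stand-in), an association TSV, a manifest, and `truth.json`. The
#' bundle plants, by construction:
#' \itemize{
#'   \item three gene-pair similarity regimes: identical (S = 1), disjoint
#'     (S = -1), and partial overlap at `feature_overlap_level`;
#'   \item one disease name per mapping tier (direct, half-ambiguous via
#'     comma rotation, xref, ambiguous, unmappable);
#'   \item one disease-gene path per requested length, with the exact
#'     optimized confidence evaluated in closed form by the generator.
#' }
#' The truth file freezes all expectations so pipeline output can be checked
#' against them.
#'
#' @param spec a [fixture_spec()].
#' @param dir output directory (created if needed).
#' @return invisibly, a list with the file paths and the `truth` list.
#' @export
generate_fixture <- function(spec, dir) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  with_seed(spec$seed, {
    ns <- spec$n_sources
    lvl <- spec$feature_overlap_level
    genes <- sprintf("G%03d", seq_len(spec$n_genes))
    feats <- stats::setNames(
      replicate(spec$n_genes, replicate(ns, character(0), simplify = FALSE),
                simplify = FALSE), genes)

    truth <- list(similarity_regimes = list(), tiers = list(), paths = list(),
                  params = unclass(spec))

    # --- planted similarity regimes on G001..G006 -----------------------
    idn <- planted_pair_tokens("idn", ns, 1)     # identical sets
    feats[["G001"]] <- idn$a
    feats[["G002"]] <- idn$a
    for (m in seq_len(ns)) {
      feats[["G003"]][[m]] <- sprintf("dsj.s%d.a%02d", m, 1:6)
      feats[["G004"]][[m]] <- sprintf("dsj.s%d.b%02d", m, 1:6)
    }
    par <- planted_pair_tokens("ovl", ns, lvl)
    feats[["G005"]] <- par$a
    feats[["G006"]] <- par$b
    truth$similarity_regimes <- list(
      list(gene1 = "G001", gene2 = "G002", similarity = 1),
      list(gene1 = "G003", gene2 = "G004", similarity = -1),
      list(gene1 = "G005", gene2 = "G006", similarity = par$similarity))

    # --- ontology: planted tier terms + fillers -------------------------
    terms <- list(
      list(term_id = "DOID:0000001", name = "Leukemia",
           synonyms = character(0), xrefs = character(0),
           parents = character(0)),
      list(term_id = "DOID:0000002", name = "Type 2 Diabetes Mellitus",
           synonyms = character(0), xrefs = character(0),
           parents = character(0)),
      list(term_id = "DOID:0000003", name = "Sleep Disorder",
           synonyms = "Somnipathy", xrefs = "MESH:D012893",
           parents = character(0)),
      list(term_id = "DOID:0000004", name = "Testicular Disease",
           synonyms = character(0), xrefs = character(0),
           parents = character(0)))
    mesh <- data.frame(code = "D012893", name = "Sleep Disorders",
                       stringsAsFactors = FALSE)
    adjs <- c("crimson", "cobalt", "umber", "viridian", "ochre", "sepia",
              "cerule", "amber", "ivory", "russet", "slate", "teal",
              "mauve", "fawn", "jade", "coral")
    nouns <- c("syndrome", "lesion", "dystrophy", "fibrosis", "atrophy",
               "sclerosis", "stenosis", "palsy")
    n_fill <- spec$n_terms
    fill_names <- character(0)
    if (n_fill > 0) {
      fill_names <- paste(sample(adjs, n_fill, replace = n_fill > length(adjs)),
                          sample(nouns, n_fill, replace = TRUE))
      fill_names <- make.unique(fill_names, sep = " v")
      for (i in seq_len(n_fill)) {
        parent <- if (i > 1 && stats::runif(1) < 0.6) {
          sprintf("DOID:%07d", 4L + sample.int(i - 1L, 1L))
        } else character(0)
        terms[[length(terms) + 1L]] <- list(
          term_id = sprintf("DOID:%07d", 4L + i), name = fill_names[i],
          synonyms = character(0), xrefs = character(0), parents = parent)
      }
    }

    # --- planted mapping-tier names -------------------------------------
    truth$tiers <- list(
      list(name = "Leukemia", tier = "direct", score = 1,
           term_ids = "DOID:0000001"),
      list(name = "Diabetes, Type 2", tier = "half_ambiguous", score = 0.5,
           term_ids = "DOID:0000002"),
      list(name = "Sleep Disorders", tier = "xref", score = 1,
           term_ids = "DOID:0000003"),
      list(name = "Testicular Neoplasms", tier = "ambiguous", score = 0.25,
           term_ids = "DOID:0000004"),
      list(name = "bqz77 assay", tier = "unmapped", score = 0,
           term_ids = character(0)))

    # --- planted paths ---------------------------------------------------
    # length 1: direct term -- gene association, confidence 100
    # length 2: ambiguous name --SC-- term -- gene
    # length 3: ambiguous name --SC-- term -- g --S-- g'
    # length 4: as 3 with one extra is-a hop on the disease side
    assoc <- list(c("Leukemia", "CANCER", "G001"),
                  c("Sleep Disorders", "PSYCH", "G002"),
                  c("Testicular Neoplasms", "CANCER", "G003"),
                  c("bqz77 assay", "OTHER", "G004"))
    path_words <- c("quorin", "velthar", "ospren", "drimel")
    next_gene <- 7L
    next_term <- 4L + n_fill
    for (k in seq_along(spec$planted_path_lengths)) {
      L <- spec$planted_path_lengths[k]
      if (L == 1L) {
        tid <- sprintf("DOID:%07d", next_term + 1L)
        next_term <- next_term + 1L
        tn <- paste(path_words[1 + (k %% length(path_words))], "root",
                    k, "disease")
        terms[[length(terms) + 1L]] <- list(term_id = tid, name = tn,
                                            synonyms = character(0),
                                            xrefs = character(0),
                                            parents = character(0))
        g <- sprintf("G%03d", next_gene); next_gene <- next_gene + 1L
        assoc[[length(assoc) + 1L]] <- c(tn, "PLANT", g)
        truth$paths[[k]] <- list(disease = tid, gene = g, length = 1L,
                                 nodes = c(tid, g), confidence = 100)
        next
      }
      w <- paste0(path_words[1 + ((k - 1) %% length(path_words))], k)
      qname <- paste(w, "neoplasms")       # ambiguous-tier query
      tname <- paste(w, "disease")
      tid <- sprintf("DOID:%07d", next_term + 1L)
      next_term <- next_term + 1L
      terms[[length(terms) + 1L]] <- list(term_id = tid, name = tname,
                                          synonyms = character(0),
                                          xrefs = character(0),
                                          parents = character(0))
      sc <- 0.25                           # (0.5 * 0.5): one shared word
      nodes <- c(qname, tid)
      sc_prod <- sc
      anchor_name <- tname                 # GAD name anchoring g1's edge
      if (L == 4L) {                       # extra is-a hop below tid
        tid2 <- sprintf("DOID:%07d", next_term + 1L)
        next_term <- next_term + 1L
        sub_name <- paste(w, "disease sub form")
        terms[[length(terms) + 1L]] <- list(term_id = tid2,
                                            name = sub_name,
                                            synonyms = character(0),
                                            xrefs = character(0),
                                            parents = tid)
        # query maps to tid (argmax over shared-token terms must stay tid):
        # "w neoplasms" vs "w disease" scores 0.25; vs "w disease sub form"
        # scores 0.5 * 0.125 = 0.0625 < 0.25, so tid stays the anchor
        nodes <- c(qname, tid, tid2)
        sc_prod <- sc * 1
        anchor_name <- sub_name
      }
      # the query name enters the network only through an association row;
      # give it one pointing at a dead-end helper gene (no features, hence
      # no gene-gene edges and no shortcut)
      g_extra <- sprintf("G%03d", next_gene); next_gene <- next_gene + 1L
      assoc[[length(assoc) + 1L]] <- c(qname, "PLANT", g_extra)
      g1 <- sprintf("G%03d", next_gene); next_gene <- next_gene + 1L
      assoc[[length(assoc) + 1L]] <- c(anchor_name, "PLANT", g1)
      nodes <- c(nodes, g1)
      s_prod <- 1
      if (L >= 3L) {
        g2 <- sprintf("G%03d", next_gene); next_gene <- next_gene + 1L
        pp <- planted_pair_tokens(paste0("pth", k), ns, lvl)
        feats[[g1]] <- pp$a
        feats[[g2]] <- pp$b
        nodes <- c(nodes, g2)
        s_prod <- (pp$similarity + 1) / 2
      }
      truth$paths[[k]] <- list(disease = qname,
                               gene = nodes[length(nodes)],
                               length = L, nodes = nodes,
                               confidence = 10^sc_prod * 10^s_prod)
    }
    if (next_gene - 1L > spec$n_genes) {
      stop_arg("n_genes too small for the requested planted paths")
    }

    # --- filler genes and associations ----------------------------------
    filler_genes <- genes[seq.int(next_gene, spec$n_genes)]
    pool <- sprintf("bulk.f%03d", 1:40)
    for (g in filler_genes) {
      for (m in seq_len(ns)) {
        feats[[g]][[m]] <- sample(pool, sample(3:8, 1))
      }
    }
    n_fill_assoc <- max(0L, spec$n_associations - length(assoc))
    if (n_fill_assoc > 0 && length(fill_names) && length(filler_genes)) {
      for (i in seq_len(n_fill_assoc)) {
        assoc[[length(assoc) + 1L]] <- c(sample(fill_names, 1), "FILLER",
                                         sample(filler_genes, 1))
      }
    }

    # --- write the bundle ------------------------------------------------
    src_paths <- file.path(dir, sprintf("source%d.tsv", seq_len(ns)))
    for (m in seq_len(ns)) {
      rows <- vapply(genes, function(g) {
        paste0(g, "\t", paste(feats[[g]][[m]], collapse = ";"))
      }, "")
      writeLines(rows, src_paths[m])
    }
    onto <- structure(stats::setNames(terms,
                                      vapply(terms, `[[`, "", "term_id")),
                      class = "disease_ontology")
    obo_path <- file.path(dir, "ontology.obo")
    write_obo(onto, obo_path)
    mesh_path <- file.path(dir, "mesh.tsv")
    utils::write.table(mesh, mesh_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    assoc_path <- file.path(dir, "associations.tsv")
    writeLines(c("Disease\tDis_class\tGene",
                 vapply(assoc, paste, "", collapse = "\t")), assoc_path)
    manifest_path <- file.path(dir, "manifest.yaml")
    yaml::write_yaml(list(
      sources = lapply(seq_len(ns), function(m)
        list(name = sprintf("source%d", m),
             path = basename(src_paths[m]))),
      ontology = basename(obo_path),
      thesauri = list(list(name = "MESH", path = basename(mesh_path))),
      associations = basename(assoc_path),
      threshold = 0, ambiguous_floor = 0.2, seed = spec$seed
    ), manifest_path)
    truth_path <- file.path(dir, "truth.json")
    jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    invisible(list(dir = dir, manifest = manifest_path, truth = truth,
                   truth_path = truth_path))
  })
}
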