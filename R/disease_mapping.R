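# Disease-name tokenization, word initial values, name-pair similarity, and
# the four-tier mapping cascade onto ontology terms.

#' Tokenize a disease name with comma rotation
#'
#' Splits a name into case-folded words. When a comma is present, the segment
#' after the first comma is rotated in front of the segment before it, so
#' "Diabetes, Type 2" becomes `type 2 diabetes` -- inverted-header disease
#' names put the head noun first. Further commas act as plain separators;
#' punctuation other than commas is stripped.
#'
#' @param name a single non-blank disease name.
#' @return character vector of tokens, in rotated order.
#' @examples
#' tokenize_disease_name("Diabetes, Type 2") # "type" "2" "diabetes"
#' @export
tokenize_disease_name <- function(name) {
  if (!is.character(name) || length(name) != 1L || is.na(name) ||
      !nzchar(trimws(name))) {
    stop_arg("`name` must be a single non-blank string")
  }
  x <- norm_name(name, keep_comma = TRUE)
  if (grepl(",", x, fixed = TRUE)) {
    head_part <- sub(",.*$", "", x)
    tail_part <- sub("^[^,]*,", "", x)
    tail_part <- gsub(",", " ", tail_part, fixed = TRUE)
    x <- paste(tail_part, head_part)
  }
  x <- gsub(",", " ", x, fixed = TRUE)
  toks <- strsplit(trimws(gsub("[[:space:]]+", " ", x)), " ", fixed = TRUE)[[1]]
  toks[nzchar(toks)]
}

#' Assign initial values to a token list
#'
#' The last word of a tokenized disease name carries the most meaning
#' ("diabetes" over "type"), so values halve from back to front, the first
#' word duplicating the second, and the whole vector is rescaled to sum to 1.
#' A single-word name gets value 1.
#'
#' @param tokens character vector of tokens (length >= 1).
#' @return numeric vector of initial values aligned to `tokens`, summing to 1.
#' @examples
#' assign_initial_values(c("type", "2", "diabetes", "mellitus"))
#' # 0.125 0.125 0.250 0.500
#' @export
assign_initial_values <- function(tokens) {
  k <- length(tokens)
  if (k < 1L) stop_arg("empty token list")
  if (k == 1L) return(1)
  u <- numeric(k)
  u[k] <- 1
  for (i in seq.int(k - 1L, 1L)) u[i] <- u[i + 1L] / 2
  u[1L] <- u[2L]
  u / sum(u)
}

#' Token list with initial values
#'
#' Convenience wrapper: tokenize a raw name and attach initial values.
#'
#' @param name raw disease name.
#' @return a `token_list`: list with `tokens` and `iv`.
#' @export
token_list <- function(name) {
  toks <- tokenize_disease_name(name)
  structure(list(tokens = toks, iv = assign_initial_values(toks)),
            class = "token_list")
}

#' Disease-name similarity score
#'
#' For token lists m, n with initial values IV, the score is
#' \deqn{SC(m, n) = \Big(\sum_s IV_s \varphi_s\Big)\Big(\sum_t IV_t \omega_t\Big)}
#' where \eqn{\varphi_s = 1} iff token s of m occurs among n's tokens (and
#' symmetrically for \eqn{\omega}). The score lies in \[0, 1\]: 1 iff the
#' token sets are equal, 0 iff they are disjoint.
#'
#' @param m,n disease names (strings) or `token_list` objects.
#' @return similarity score in \[0, 1\].
#' @examples
#' disease_similarity("Diabetes, Type 2", "Type 2 Diabetes Mellitus") # 0.5
#' disease_similarity("Testicular Neoplasms", "Testicular Disease")   # 0.25
#' @export
disease_similarity <- function(m, n) {
  if (!inherits(m, "token_list")) m <- token_list(m)
  if (!inherits(n, "token_list")) n <- token_list(n)
  phi <- m$tokens %in% n$tokens
  omega <- n$tokens %in% m$tokens
  sum(m$iv[phi]) * sum(n$iv[omega])
}

# Per-term token index: list of token vectors for term names (used by the
# half-ambiguous and ambiguous tiers).
term_name_tokens <- function(ontology) {
  lapply(ontology, function(t) tokenize_disease_name(t$name))
}

#' Map a free-text disease name onto ontology terms
#'
#' Four-tier cascade; the first tier that yields a hit wins:
#' \enumerate{
#'   \item \strong{direct} -- the normalized name equals a term's name or one
#'     of its synonyms; score 1.
#'   \item \strong{half_ambiguous} -- after comma rotation, the query's token
#'     set equals, or is a subset of, a term-name token set; score is the
#'     name similarity [disease_similarity()].
#'   \item \strong{xref} -- the name matches an entry of a supplementary
#'     thesaurus whose code appears among a term's cross-references; score 1.
#'   \item \strong{ambiguous} -- among terms sharing at least one token, the
#'     ones maximizing [disease_similarity()] are taken, provided that score
#'     reaches `ambiguous_floor`.
#' }
#' Otherwise the name is \strong{unmapped} (score 0) -- a valid outcome,
#' recorded apart as a non-disease name.
#'
#' @param name free-text disease name.
#' @param ontology a `disease_ontology` (see [read_obo()]).
#' @param thesauri optional named list of thesauri, each a data.frame with
#'   columns `code`, `name`; names give the thesaurus prefix used in xrefs
#'   (e.g. `MESH` for xref `MESH:D012893`).
#' @param ambiguous_floor minimal similarity accepted in the ambiguous tier
#'   (default 0.2, a tunable).
#' @param tier_order cascade order; the default follows the cumulative
#'   coverage ordering direct, half_ambiguous, xref, ambiguous.
#' @return a `disease_mapping`: list with `raw_name`, `tier`, `matched_terms`
#'   (data.frame `term_id`, `score`, lexicographic by `term_id`), `score`.
#' @export
map_disease <- function(name, ontology, thesauri = list(),
                        ambiguous_floor = 0.2,
                        tier_order = c("direct", "half_ambiguous",
                                       "xref", "ambiguous")) {
  stopifnot(inherits(ontology, "disease_ontology"))
  if (!(ambiguous_floor > 0 && ambiguous_floor <= 1)) {
    stop_arg("`ambiguous_floor` must be in (0, 1]")
  }
  tier_order <- match.arg(tier_order, several.ok = TRUE)
  q_norm <- norm_name(name)
  q <- token_list(name)
  name_tok <- term_name_tokens(ontology)
  ids <- vapply(ontology, `[[`, "", "term_id")

  hit <- function(tier, term_ids, scores) {
    ord <- order(term_ids)
    structure(list(
      raw_name = name, tier = tier,
      matched_terms = data.frame(term_id = term_ids[ord],
                                 score = scores[ord],
                                 stringsAsFactors = FALSE),
      score = max(scores)
    ), class = "disease_mapping")
  }

  for (tier in tier_order) {
    res <- switch(tier,
      direct = {
        m <- vapply(ontology, function(t) {
          q_norm == norm_name(t$name) ||
            q_norm %in% norm_name(t$synonyms)
        }, logical(1))
        if (any(m)) hit("direct", ids[m], rep(1, sum(m))) else NULL
      },
      half_ambiguous = {
        m <- vapply(name_tok, function(tt) {
          all(q$tokens %in% tt)
        }, logical(1))
        if (any(m)) {
          sc <- vapply(which(m), function(i) {
            disease_similarity(q, structure(
              list(tokens = name_tok[[i]],
                   iv = assign_initial_values(name_tok[[i]])),
              class = "token_list"))
          }, numeric(1))
          hit("half_ambiguous", ids[which(m)], sc)
        } else NULL
      },
      xref = {
        codes <- character(0)
        for (th_name in names(thesauri)) {
          th <- thesauri[[th_name]]
          cm <- norm_name(th$name) == q_norm
          if (any(cm)) {
            codes <- c(codes, paste0(th_name, ":", th$code[cm]))
          }
        }
        if (length(codes)) {
          m <- vapply(ontology, function(t) any(codes %in% t$xrefs),
                      logical(1))
          if (any(m)) hit("xref", ids[m], rep(1, sum(m))) else NULL
        } else NULL
      },
      ambiguous = {
        shares <- vapply(name_tok, function(tt) any(q$tokens %in% tt),
                         logical(1))
        if (any(shares)) {
          sc <- vapply(which(shares), function(i) {
            disease_similarity(q, structure(
              list(tokens = name_tok[[i]],
                   iv = assign_initial_values(name_tok[[i]])),
              class = "token_list"))
          }, numeric(1))
          best <- max(sc)
          if (best >= ambiguous_floor) {
            keep <- which(shares)[sc == best]
            hit("ambiguous", ids[keep], rep(best, length(keep)))
          } else NULL
        } else NULL
      })
    if (!is.null(res)) return(res)
  }
  structure(list(raw_name = name, tier = "unmapped",
                 matched_terms = data.frame(term_id = character(0),
                                            score = numeric(0),
                                            stringsAsFactors = FALSE),
                 score = 0),
            class = "disease_mapping")
}

#' @export
print.disease_mapping <- function(x, ...) {
  cat(sprintf("'%s' -> tier %s (score %.4g)\n", x$raw_name, x$tier, x$score))
  if (nrow(x$matched_terms)) {
    cat(paste0("  ", x$matched_terms$term_id, " (",
               signif(x$matched_terms$score, 4), ")", collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Map a batch of disease names
#'
#' @inheritParams map_disease
#' @param names character vector of free-text disease names.
#' @return a `disease_mapping_set`: list of [map_disease()] results, one per
#'   distinct input name, named by the raw names.
#' @export
map_diseases <- function(names, ontology, thesauri = list(),
                         ambiguous_floor = 0.2,
                         tier_order = c("direct", "half_ambiguous",
                                        "xref", "ambiguous")) {
  names <- unique(names)
  out <- lapply(names, map_disease, ontology = ontology, thesauri = thesauri,
                ambiguous_floor = ambiguous_floor, tier_order = tier_order)
  names(out) <- names
  structure(out, class = "disease_mapping_set")
}

#' @export
print.disease_mapping_set <- function(x, ...) {
  tiers <- vapply(x, `[[`, "", "tier")
  cat("Disease mapping set:", length(x), "names\n")
  print(table(factor(tiers, levels = c("direct", "half_ambiguous", "xref",
                                       "ambiguous", "unmapped"))))
  invisible(x)
}

#' Write a mapping report and the chart of unmapped names
#'
#' The report is a TSV `raw_name \t tier \t term_id \t score` (one row per
#' matched term; unmapped names appear with an empty `term_id`). Unmapped
#' names are additionally written to `unmapped_path` as a separate chart.
#'
#' @param mappings a `disease_mapping_set`.
#' @param path report TSV path.
#' @param unmapped_path optional path for the unmapped-name chart.
#' @export
write_mapping_report <- function(mappings, path, unmapped_path = NULL) {
  rows <- lapply(mappings, function(m) {
    if (nrow(m$matched_terms) == 0L) {
      data.frame(raw_name = m$raw_name, tier = m$tier, term_id = "",
                 score = 0, stringsAsFactors = FALSE)
    } else {
      data.frame(raw_name = m$raw_name, tier = m$tier,
                 term_id = m$matched_terms$term_id,
                 score = m$matched_terms$score, stringsAsFactors = FALSE)
    }
  })
  report <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  report <- report[order(report$raw_name, report$term_id), , drop = FALSE]
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(unmapped_path)) {
    un <- sort(report$raw_name[report$tier == "unmapped"])
    writeLines(un, unmapped_path)
  }
  invisible(path)
}
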