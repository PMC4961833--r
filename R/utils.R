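# Shared string normalization. Feature tokens and disease-name words are
# database identifiers / vocabulary words, so normalization is case-fold +
# trim only -- no stemming, no plural folding.

norm_token <- function(x) {
  tolower(trimws(x))
}

#' Normalize a name for exact-string comparison
#'
#' Case-folds, strips punctuation except commas (which carry meaning for
#' word rotation), and collapses runs of whitespace.
#'
#' @param x character vector.
#' @param keep_comma keep commas (needed before tokenization)?
#' @return normalized character vector.
#' @keywords internal
norm_name <- function(x, keep_comma = FALSE) {
  x <- tolower(x)
  pat <- if (keep_comma) "[^[:alnum:][:space:],]+" else "[^[:alnum:][:space:]]+"
  x <- gsub(pat, " ", x)
  x <- gsub("[[:space:]]+", " ", x)
  trimws(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_arg <- function(...) stop(..., call. = FALSE)
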