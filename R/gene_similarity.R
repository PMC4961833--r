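# Gene similarity from multi-source feature lists, node significance, and
# the thresholded gene relation network.

#' Build a collection of gene feature vectors
#'
#' A gene feature vector is a gene symbol plus one feature-token set per
#' source database. All genes in a collection share the same source
#' configuration; a gene absent from a source carries an empty set there.
#'
#' @param features named list (names = gene symbols); each element a list of
#'   `n_sources` character vectors of feature tokens.
#' @param sources character vector of source names (defines `n_sources`).
#' @return an object of class `gene_features`: a named list of per-gene
#'   token-set lists, with attribute `sources`.
#' @examples
#' gene_features(
#'   list(TP53 = list(c("p1", "p2"), "go1"), EGFR = list("p1", character())),
#'   sources = c("pathways", "go")
#' )
#' @export
gene_features <- function(features, sources) {
  if (length(sources) < 1L) stop_arg("at least one source is required")
  syms <- names(features)
  if (is.null(syms) || any(!nzchar(syms))) {
    stop_arg("every gene feature vector needs a non-empty gene symbol")
  }
  if (anyDuplicated(syms)) {
    stop_arg("duplicate gene symbols: ",
             paste(unique(syms[duplicated(syms)]), collapse = ", "))
  }
  n <- length(sources)
  features <- lapply(features, function(f) {
    if (length(f) != n) {
      stop_arg("each gene must have exactly ", n,
               " feature sets (one per source)")
    }
    lapply(f, function(s) unique(norm_token(as.character(s))))
  })
  names(features) <- toupper(syms)
  structure(features, sources = sources, class = "gene_features")
}

#' @export
print.gene_features <- function(x, ...) {
  cat("Gene feature collection: ", length(x), " genes, ",
      length(attr(x, "sources")), " sources (",
      paste(attr(x, "sources"), collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Set-overlap score of two feature lists
#'
#' For token sets L1, L2 the score is
#' \deqn{(|L1 \cap L2| - |L1 \cup L2|/2) / (|L1 \cup L2|/2),}
#' i.e. 2J - 1 for Jaccard index J: 1 for identical non-empty sets, -1 for
#' disjoint non-empty sets. When both sets are empty there is no evidence and
#' `NA_real_` is returned; callers treat that source as contributing nothing.
#'
#' @param l1,l2 character vectors of feature tokens.
#' @return a score in \[-1, 1\], or `NA_real_` when the union is empty.
#' @examples
#' source_overlap_score(c("a", "b", "c"), c("b", "c", "d")) # 0
#' @export
source_overlap_score <- function(l1, l2) {
  l1 <- unique(norm_token(as.character(l1)))
  l2 <- unique(norm_token(as.character(l2)))
  u <- length(union(l1, l2))
  if (u == 0L) return(NA_real_)
  i <- length(intersect(l1, l2))
  (i - u / 2) / (u / 2)
}

#' Weighted gene-pair similarity
#'
#' Weighted sum over sources of the per-source overlap score,
#' \eqn{S(g_s, g_t) = \sum_m \alpha_m \, score_m}{S = sum alpha_m * score_m}
#' with \eqn{\sum \alpha_m = 1}. Sources where both genes have empty feature
#' sets carry no evidence; the weights are renormalized over evidence-bearing
#' sources. If no source bears evidence the pair is neutral and the
#' similarity is 0.
#'
#' @param gs,gt either gene symbols indexing into `collection`, or bare lists
#'   of per-source token vectors.
#' @param weights numeric vector of per-source weights summing to 1; default
#'   uniform `1/n`.
#' @param collection a [gene_features()] collection (required when `gs`/`gt`
#'   are symbols).
#' @return similarity in \[-1, 1\]; symmetric in `gs`, `gt`.
#' @examples
#' gf <- gene_features(
#'   list(A = list(c("x", "y"), "g1"), B = list(c("x", "y"), "g1")),
#'   sources = c("s1", "s2")
#' )
#' gene_similarity("A", "B", collection = gf) # 1
#' @export
gene_similarity <- function(gs, gt, weights = NULL, collection = NULL) {
  if (is.character(gs) && length(gs) == 1L) {
    if (is.null(collection)) stop_arg("`collection` needed for symbol lookup")
    gs <- collection[[toupper(gs)]] %||% stop_arg("unknown gene: ", gs)
  }
  if (is.character(gt) && length(gt) == 1L) {
    if (is.null(collection)) stop_arg("`collection` needed for symbol lookup")
    gt <- collection[[toupper(gt)]] %||% stop_arg("unknown gene: ", gt)
  }
  n <- length(gs)
  if (length(gt) != n) {
    stop_arg("source configuration mismatch: ", n, " vs ", length(gt),
             " feature sets")
  }
  if (is.null(weights)) weights <- rep(1 / n, n)
  if (length(weights) != n) stop_arg("need one weight per source")
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-9) {
    stop_arg("weights must be non-negative and sum to 1")
  }
  sc <- vapply(seq_len(n), function(m) source_overlap_score(gs[[m]], gt[[m]]),
               numeric(1))
  ok <- !is.na(sc)
  if (!any(ok)) return(0)
  w <- weights[ok]
  if (sum(w) == 0) return(0)
  sum(sc[ok] * w / sum(w))
}

#' Pairwise gene similarity matrix
#'
#' @param collection a [gene_features()] collection.
#' @param weights optional per-source weights (default uniform).
#' @return symmetric numeric matrix with unit diagonal, dimnames = gene
#'   symbols, entries in \[-1, 1\].
#' @export
similarity_matrix <- function(collection, weights = NULL) {
  stopifnot(inherits(collection, "gene_features"))
  syms <- names(collection)
  n <- length(syms)
  m <- diag(1, n)
  dimnames(m) <- list(syms, syms)
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        s <- gene_similarity(collection[[i]], collection[[j]],
                             weights = weights)
        m[i, j] <- m[j, i] <- s
      }
    }
  }
  m
}

#' Node significance in the similarity matrix
#'
#' Diagnostic importance of a gene: the signs of its similarities to every
#' other gene are summed, scaled by the number of other genes, and passed
#' through the exponential,
#' \deqn{Sig(n) = \exp(|\sum_{m \ne n} sign(S(g_m, g_n))| / (N - 1)) \in [1, e].}
#' A gene consistently similar (or consistently dissimilar) to all others
#' scores near e; a gene with balanced signs scores near 1. With
#' `reading = "raw"` the raw similarities are summed instead of their signs.
#' The value is a diagnostic to guide threshold choice; it does not feed the
#' network construction.
#'
#' @param gene gene symbol (must index `m`).
#' @param m similarity matrix from [similarity_matrix()].
#' @param reading `"sign"` (default) or `"raw"`.
#' @return significance value; in \[1, e\] under the sign reading.
#' @export
node_significance <- function(gene, m, reading = c("sign", "raw")) {
  reading <- match.arg(reading)
  gene <- toupper(gene)
  if (!gene %in% rownames(m)) stop_arg("unknown gene: ", gene)
  n <- nrow(m)
  if (n < 2L) stop_arg("node significance needs at least 2 genes")
  s <- m[gene, setdiff(rownames(m), gene)]
  v <- if (reading == "sign") sum(sign(s)) else sum(s)
  exp(abs(v) / (n - 1L))
}

#' Thresholded gene relation network
#'
#' Keeps exactly the gene pairs whose similarity strictly exceeds the
#' threshold (default 0, so non-similar pairs with S <= 0 are dropped).
#'
#' @param m similarity matrix.
#' @param threshold activation threshold in \[-1, 1\].
#' @return data.frame with columns `gene1`, `gene2`, `weight`, ordered
#'   lexicographically by endpoint pair, with `gene1 < gene2` per row.
#' @export
build_gene_network <- function(m, threshold = 0) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      is.na(threshold) || threshold < -1 || threshold > 1) {
    stop_arg("`threshold` must be a single value in [-1, 1]")
  }
  syms <- rownames(m)
  idx <- which(upper.tri(m) & m > threshold, arr.ind = TRUE)
  edges <- data.frame(
    gene1 = syms[idx[, 1L]],
    gene2 = syms[idx[, 2L]],
    weight = m[idx],
    stringsAsFactors = FALSE
  )
  swap <- edges$gene1 > edges$gene2
  if (any(swap)) {
    tmp <- edges$gene1[swap]
    edges$gene1[swap] <- edges$gene2[swap]
    edges$gene2[swap] <- tmp
  }
  edges <- edges[order(edges$gene1, edges$gene2), , drop = FALSE]
  rownames(edges) <- NULL
  edges
}

#' Write a gene edge list as TSV
#'
#' Columns `gene1 \t gene2 \t weight`, deterministic lexicographic order.
#'
#' @param edges data.frame from [build_gene_network()].
#' @param path output file.
#' @export
write_gene_network <- function(edges, path) {
  edges <- edges[order(edges$gene1, edges$gene2), , drop = FALSE]
  utils::write.table(edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
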