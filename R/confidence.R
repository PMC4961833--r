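# Path confidence: the raw product-of-scores confidence and its optimized
# form, which stays strictly positive whenever a path exists.

#' Construct a scored path through the network
#'
#' Validates that consecutive nodes are adjacent, collects the per-edge
#' scores, and partitions them into disease-side scores (weights of
#' `disease_disease` edges, the name-similarity SC values) and gene-side
#' scores (weights of `gene_gene` edges, the similarity S values).
#' `gene_disease` edges are the curated anchors and contribute the
#' multiplicative identity.
#'
#' @param net a `hetero_network`.
#' @param nodes ordered node ids from a disease to a gene (length >= 2).
#' @return a `scored_path`: list with `nodes`, `edges` (data.frame),
#'   `sc_scores`, `s_scores`, `raw_confidence`, `confidence`.
#' @export
scored_path <- function(net, nodes) {
  stopifnot(inherits(net, "hetero_network"))
  if (length(nodes) < 2L) stop_arg("a path needs at least 2 nodes")
  if (anyDuplicated(nodes)) stop_arg("path revisits a node")
  e <- net$edges
  key <- paste(pmin(e$node1, e$node2), pmax(e$node1, e$node2), sep = "\r")
  steps <- lapply(seq_len(length(nodes) - 1L), function(i) {
    k <- paste(min(nodes[i], nodes[i + 1L]),
               max(nodes[i], nodes[i + 1L]), sep = "\r")
    hit <- which(key == k)
    if (!length(hit)) {
      stop_arg("not a path: no edge between ", nodes[i], " and ",
               nodes[i + 1L])
    }
    e[hit[1L], , drop = FALSE]
  })
  edges <- do.call(rbind, steps)
  rownames(edges) <- NULL
  p <- structure(list(
    nodes = nodes,
    edges = edges,
    sc_scores = edges$weight[edges$edge_type == "disease_disease"],
    s_scores = edges$weight[edges$edge_type == "gene_gene"]
  ), class = "scored_path")
  p$raw_confidence <- raw_confidence(p)
  p$confidence <- path_confidence(p)
  p
}

check_scored_path <- function(path) {
  if (!inherits(path, "scored_path")) {
    stop_arg("`path` must be a scored_path (see scored_path())")
  }
  path
}

#' Raw disease-gene path confidence
#'
#' The product of all disease-side name-similarity scores (SC) and all
#' gene-side similarity scores (S) along the path; empty score groups
#' contribute 1, so a direct curated association scores 1. A single S = 0
#' edge annihilates the product -- the defect the optimized
#' [path_confidence()] repairs.
#'
#' @param path a `scored_path`.
#' @return the raw confidence (real; can be 0 or negative via S < 0).
#' @export
raw_confidence <- function(path) {
  path <- check_scored_path(path)
  prod(path$sc_scores) * prod(path$s_scores)
}

#' Optimized disease-gene path confidence
#'
#' \deqn{DGI'(d, g) = SC' \times S', \quad SC' = 10^{\prod SC}, \quad
#'       S' = 10^{\prod (S + 1)/2}.}
#' The affine map (S+1)/2 carries gene similarities from \[-1, 1\] into
#' \[0, 1\], so the confidence is strictly positive for every existing path;
#' empty products are 1, hence a direct verified association scores
#' 10 x 10 = 100. Range: (0, 100], with 100 meaning a verified interaction.
#'
#' @param path a `scored_path`.
#' @return confidence in (0, 100].
#' @export
path_confidence <- function(path) {
  path <- check_scored_path(path)
  10^prod(path$sc_scores) * 10^prod((path$s_scores + 1) / 2)
}

#' @export
print.scored_path <- function(x, ...) {
  cat("Scored path:", paste(x$nodes, collapse = " -- "), "\n")
  cat(sprintf("  edges: %d | raw confidence %.6g | confidence %.6g\n",
              nrow(x$edges), x$raw_confidence, x$confidence))
  invisible(x)
}

#' Serialize a scored path as a JSON record
#'
#' @param path a `scored_path`.
#' @param file optional path; if `NULL`, the JSON string is returned.
#' @return the JSON string, invisibly when written to a file.
#' @export
path_to_json <- function(path, file = NULL) {
  path <- check_scored_path(path)
  rec <- list(
    disease = path$nodes[1L],
    gene = path$nodes[length(path$nodes)],
    nodes = path$nodes,
    edge_scores = lapply(seq_len(nrow(path$edges)), function(i) {
      list(node1 = path$edges$node1[i], node2 = path$edges$node2[i],
           edge_type = path$edges$edge_type[i],
           weight = path$edges$weight[i])
    }),
    raw_confidence = path$raw_confidence,
    confidence = path$confidence
  )
  js <- jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA)
  if (is.null(file)) return(js)
  writeLines(js, file)
  invisible(js)
}
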