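# Shared in-code builders for tiny ontologies and networks.

mk_term <- function(id, name, synonyms = character(0), xrefs = character(0),
                    parents = character(0)) {
  list(term_id = id, name = name, synonyms = synonyms, xrefs = xrefs,
       parents = parents)
}

mk_ontology <- function(...) {
  terms <- list(...)
  structure(stats::setNames(terms, vapply(terms, `[[`, "", "term_id")),
            class = "disease_ontology")
}

c_onto <- function(onto, term) {
  onto[[term$term_id]] <- term
  structure(onto, class = "disease_ontology")
}

# the four-tier toy ontology used across mapping tests
toy_ontology <- function() {
  mk_ontology(
    mk_term("DOID:1", "Leukemia"),
    mk_term("DOID:2", "Type 2 Diabetes Mellitus"),
    mk_term("DOID:3", "Sleep Disorder", xrefs = "MESH:D012893"),
    mk_term("DOID:4", "Testicular Disease", parents = "DOID:1")
  )
}

toy_thesauri <- function() {
  list(MESH = data.frame(code = "D012893", name = "Sleep Disorders",
                         stringsAsFactors = FALSE))
}

# build a hetero_network straight from an edge table (node types inferred
# from prefixes: ids starting with "g" are genes)
mk_network <- function(node1, node2, edge_type, weight = 1) {
  edges <- data.frame(node1 = node1, node2 = node2, edge_type = edge_type,
                      weight = weight, stringsAsFactors = FALSE)
  ids <- unique(c(node1, node2))
  nodes <- data.frame(node = ids,
                      node_type = ifelse(grepl("^g", ids), "gene", "disease"),
                      stringsAsFactors = FALSE)
  gdnet:::new_hetero_network(nodes, edges)
}

# random typed network: genes g1..gn, diseases d1..dm, edge prob p
random_network <- function(n_gene, n_dis, p) {
  ids <- c(paste0("g", seq_len(n_gene)), paste0("d", seq_len(n_dis)))
  pairs <- utils::combn(ids, 2)
  keep <- stats::runif(ncol(pairs)) < p
  pairs <- pairs[, keep, drop = FALSE]
  if (!ncol(pairs)) pairs <- utils::combn(ids, 2)[, 1, drop = FALSE]
  a <- pairs[1, ]; b <- pairs[2, ]
  is_g <- function(x) grepl("^g", x)
  ty <- ifelse(is_g(a) & is_g(b), "gene_gene",
               ifelse(!is_g(a) & !is_g(b), "disease_disease",
                      "gene_disease"))
  w <- ifelse(ty == "gene_disease", 1, round(stats::runif(length(ty), 0.1, 1), 3))
  nodes <- data.frame(node = ids,
                      node_type = ifelse(is_g(ids), "gene", "disease"),
                      stringsAsFactors = FALSE)
  gdnet:::new_hetero_network(
    nodes, data.frame(node1 = a, node2 = b, edge_type = ty, weight = w,
                      stringsAsFactors = FALSE))
}

# igraph shortest-path oracle: length of shortest path, Inf if disconnected
oracle_shortest <- function(net, from, to) {
  g <- igraph::graph_from_data_frame(net$edges[, c("node1", "node2")],
                                     directed = FALSE,
                                     vertices = net$nodes$node)
  igraph::distances(g, v = from, to = to, weights = NA)[1, 1]
}
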