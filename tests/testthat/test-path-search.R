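test_that("node priority follows W(n) = e^(Eo-Ei) * Eo * eps", {
  # g1 has degree 3 with 1 edge to the input term d1
  net <- mk_network(c("d1", "g1", "g1"), c("g1", "g2", "g3"),
                    c("gene_disease", "gene_gene", "gene_gene"),
                    c(1, 0.5, 0.5))
  expect_equal(node_priority("g1", net, input_terms = "d1", epsilon = 1),
               2 * exp(1))
  # a node already held in a frontier list scores zero
  expect_equal(node_priority("g1", net, input_terms = "d1",
                             frontier_nodes = "g1"), 0)
  # isolated node: Eo = 0 annihilates
  net2 <- gdnet:::new_hetero_network(
    data.frame(node = c("g1", "g2", "d1"),
               node_type = c("gene", "gene", "disease"),
               stringsAsFactors = FALSE),
    data.frame(node1 = "g1", node2 = "g2", edge_type = "gene_gene",
               weight = 0.5, stringsAsFactors = FALSE))
  expect_equal(node_priority("d1", net2), 0)
  expect_error(node_priority("nope", net), "unknown node")
  # the random factor stays in [0.5, 1] times the base
  set.seed(1)
  w <- replicate(50, node_priority("g1", net, input_terms = "d1"))
  expect_true(all(w >= exp(1) * 2 * 0.5 - 1e-12 & w <= exp(1) * 2 + 1e-12))
})

test_that("direct neighbors and disconnected pairs behave at the bounds", {
  net <- mk_network(c("d1", "g1", "d2"), c("g1", "g2", "d3"),
                    c("gene_disease", "gene_gene", "disease_disease"),
                    c(1, 0.5, 0.8))
  p <- find_path(net, "d1", "g1", maxlength = 1, exhaustive = TRUE)
  expect_identical(p$nodes, c("d1", "g1"))
  expect_equal(p$confidence, 100)
  # d2/d3 component never reaches g1
  expect_null(find_path(net, "d2", "g1", maxlength = 5, exhaustive = TRUE))
  expect_null(find_path(net, "d2", "g1", maxlength = 5))
  expect_error(find_path(net, "zz", "g1", 2), "unknown term")
  expect_error(find_path(net, "d1", "g1", 0), "positive")
})

test_that("a unique 3-edge path is found at maxlength 3 and missed at 2", {
  # d1 - d2 - g1 - g2 plus decoys
  net <- mk_network(c("d1", "d2", "g1", "d1", "g3"),
                    c("d2", "g1", "g2", "g3", "g4"),
                    c("disease_disease", "gene_disease", "gene_gene",
                      "gene_disease", "gene_gene"),
                    c(0.5, 1, 0.6, 1, 0.9))
  p <- find_path(net, "d1", "g2", maxlength = 3, exhaustive = TRUE)
  expect_identical(p$nodes, c("d1", "d2", "g1", "g2"))
  expect_equal(p$confidence, 10^0.5 * 10^0.8)
  expect_null(find_path(net, "d1", "g2", maxlength = 2, exhaustive = TRUE))
})

test_that("exhaustive mode agrees with the brute-force oracle on random
           graphs", {
  set.seed(97)
  for (i in 1:40) {
    net <- random_network(sample(3:15, 1), sample(3:15, 1),
                          stats::runif(1, 0.04, 0.25))
    genes <- net$nodes$node[net$nodes$node_type == "gene"]
    dis <- net$nodes$node[net$nodes$node_type == "disease"]
    d <- sample(dis, 1)
    g <- sample(genes, 1)
    maxlen <- sample(1:6, 1)
    truth <- oracle_shortest(net, d, g)
    got <- find_path(net, d, g, maxlength = maxlen, exhaustive = TRUE)
    if (is.finite(truth) && truth <= maxlen) {
      expect_false(is.null(got))
      expect_equal(length(got$nodes) - 1L, unname(truth))
    } else {
      expect_null(got)
    }
  }
})

test_that("heuristic mode is sound and seed-reproducible", {
  set.seed(55)
  for (i in 1:15) {
    net <- random_network(sample(4:12, 1), sample(4:12, 1),
                          stats::runif(1, 0.08, 0.3))
    genes <- net$nodes$node[net$nodes$node_type == "gene"]
    dis <- net$nodes$node[net$nodes$node_type == "disease"]
    d <- sample(dis, 1)
    g <- sample(genes, 1)
    p1 <- find_path(net, d, g, maxlength = 4, seed = 123)
    p2 <- find_path(net, d, g, maxlength = 4, seed = 123)
    expect_identical(
      if (is.null(p1)) NULL else p1$nodes,
      if (is.null(p2)) NULL else p2$nodes)
    if (!is.null(p1)) {
      # validity: scored_path() re-checks adjacency edge by edge
      expect_silent(scored_path(net, p1$nodes))
      expect_lte(length(p1$nodes) - 1L, 4L)
    }
  }
})

test_that("find_path leaves the caller's RNG stream untouched", {
  net <- mk_network("d1", "g1", "gene_disease", 1)
  set.seed(9)
  before <- .Random.seed
  invisible(find_path(net, "d1", "g1", 2, seed = 77))
  expect_identical(.Random.seed, before)
})

test_that("all_paths returns every recoverable shared-frontier path within
           the bound", {
  # two parallel length-2 routes d1-g1-g3 / d1-g2-g3
  net <- mk_network(c("d1", "d1", "g1", "g2"),
                    c("g1", "g2", "g3", "g3"),
                    c("gene_disease", "gene_disease", "gene_gene",
                      "gene_gene"),
                    c(1, 1, 0.4, 0.6))
  ps <- find_path(net, "d1", "g3", maxlength = 2, exhaustive = TRUE,
                  all_paths = TRUE)
  routes <- sort(vapply(ps, function(p) paste(p$nodes, collapse = ">"), ""))
  expect_identical(routes, c("d1>g1>g3", "d1>g2>g3"))
})
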