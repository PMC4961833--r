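toy_assembly <- function() {
  onto <- toy_ontology()
  th <- toy_thesauri()
  assoc <- data.frame(
    disease_name = c("Leukemia", "Testicular Neoplasms", "Sleep Disorders",
                     "bqz77 assay", "Leukemia"),
    disease_class = c("CANCER", "CANCER", "PSYCH", "OTHER", "CANCER"),
    gene_symbol = c("HLA-A", "GSTT1", "HLA-A", "HFE", "HLA-A"), # dup row
    stringsAsFactors = FALSE)
  gene_edges <- data.frame(gene1 = "GSTT1", gene2 = "HLA-A", weight = 0.4,
                           stringsAsFactors = FALSE)
  maps <- map_diseases(assoc$disease_name, onto, th)
  list(onto = onto, assoc = assoc, gene_edges = gene_edges, maps = maps,
       net = assemble_network(gene_edges, onto, maps, assoc,
                              genes = c("GSTT1", "HLA-A", "HFE")))
}

test_that("assembly fuses the four layers with the documented node and edge
           rules", {
  x <- toy_assembly()
  net <- x$net
  # empty inputs give an empty network
  e0 <- assemble_network()
  expect_equal(nrow(e0$nodes) + nrow(e0$edges), 0L)
  # direct- and xref-tier names collapse into term nodes; lower tiers and
  # unmapped names keep their own node
  expect_false("Leukemia" %in% net$nodes$node)
  expect_false("Sleep Disorders" %in% net$nodes$node)
  expect_true(all(c("Testicular Neoplasms", "bqz77 assay") %in%
                    net$nodes$node))
  # is-a edge DOID:4 -> DOID:1 at weight 1
  dd <- net$edges[net$edges$edge_type == "disease_disease", ]
  isa <- dd[dd$node1 == "DOID:1" & dd$node2 == "DOID:4", ]
  expect_equal(isa$weight, 1)
  # mapping edge carries the ambiguous score
  mp <- dd[dd$node1 == "DOID:4" & dd$node2 == "Testicular Neoplasms", ]
  expect_equal(mp$weight, 0.25)
  # association edges anchor at the right node, weight 1, dedup'd
  gd <- net$edges[net$edges$edge_type == "gene_disease", ]
  expect_equal(sum(gd$node1 == "DOID:1" & gd$node2 == "HLA-A"), 1L)
  expect_equal(sum(gd$node1 == "DOID:3" & gd$node2 == "HLA-A"), 1L)
  expect_equal(sum((gd$node1 == "bqz77 assay" & gd$node2 == "HFE") |
                     (gd$node1 == "HFE" & gd$node2 == "bqz77 assay")), 1L)
  expect_true(all(gd$weight == 1))
  # count conservation: distinct (anchor, gene) pairs with known genes
  expect_equal(nrow(gd), 4L)
})

test_that("unknown gene symbols are skipped and counted, missing mappings
           are an error", {
  x <- toy_assembly()
  assoc2 <- rbind(x$assoc,
                  data.frame(disease_name = "Leukemia",
                             disease_class = "CANCER",
                             gene_symbol = "NOSUCH",
                             stringsAsFactors = FALSE))
  net <- assemble_network(x$gene_edges, x$onto, x$maps, assoc2,
                          genes = c("GSTT1", "HLA-A", "HFE"))
  expect_equal(net$report$n_skipped_associations, 1L)
  expect_false("NOSUCH" %in% net$nodes$node)
  expect_error(assemble_network(x$gene_edges, x$onto,
                                x$maps[names(x$maps) != "Leukemia"],
                                x$assoc),
               "mappings missing")
})

test_that("every edge's endpoint types match its class", {
  net <- toy_assembly()$net
  ty <- stats::setNames(net$nodes$node_type, net$nodes$node)
  for (i in seq_len(nrow(net$edges))) {
    e <- net$edges[i, ]
    got <- sort(unname(ty[c(e$node1, e$node2)]))
    want <- switch(e$edge_type,
                   gene_gene = c("gene", "gene"),
                   disease_disease = c("disease", "disease"),
                   gene_disease = c("disease", "gene"))
    expect_identical(got, want)
  }
  # the constructor enforces this too
  expect_error(
    mk_network("g1", "g2", "gene_disease"),
    "endpoint types")
})

test_that("assembly is idempotent: byte-identical serialization", {
  x <- toy_assembly()
  net2 <- assemble_network(x$gene_edges, x$onto, x$maps, x$assoc,
                           genes = c("GSTT1", "HLA-A", "HFE"))
  f1 <- tempfile(); f2 <- tempfile(); n1 <- tempfile(); n2 <- tempfile()
  write_network(x$net, f1, n1)
  write_network(net2, f2, n2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(readLines(n1), readLines(n2))
})

test_that("network serialization round-trips", {
  x <- toy_assembly()
  f <- tempfile(); n <- tempfile()
  write_network(x$net, f, n)
  back <- read_network(f, n)
  expect_equal(back$nodes, x$net$nodes)
  expect_equal(back$edges, x$net$edges)
  # node types can be inferred from edge classes when the table is absent
  back2 <- read_network(f)
  ty <- stats::setNames(back2$nodes$node_type, back2$nodes$node)
  expect_identical(unname(ty["GSTT1"]), "gene")
  expect_identical(unname(ty["DOID:1"]), "disease")
})
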