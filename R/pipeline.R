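# End-to-end driver: manifest -> similarity matrix -> gene network ->
# disease mappings -> assembled heterogeneous network.

#' Run the full network-construction pipeline
#'
#' Reads every input named in a manifest, computes the gene similarity
#' matrix and thresholded gene network, maps all association disease names
#' onto the ontology, and assembles the heterogeneous network. Each stage's
#' output is returned so intermediate results can be inspected or written.
#'
#' @param manifest a manifest path or a list from [read_manifest()].
#' @return a `gdnet_pipeline` list: `manifest`, `features`, `simmat`,
#'   `gene_edges`, `ontology`, `thesauri`, `associations`, `mappings`,
#'   `network`.
#' @examples
#' \donttest{
#' dir <- tempfile("fx")
#' generate_fixture(fixture_spec(seed = 7), dir)
#' pl <- run_pipeline(file.path(dir, "manifest.yaml"))
#' pl$network
#' }
#' @export
run_pipeline <- function(manifest) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  features <- read_gene_features(manifest)
  simmat <- similarity_matrix(features, weights = manifest$sources$alpha)
  gene_edges <- build_gene_network(simmat, threshold = manifest$threshold)
  ontology <- if (!is.null(manifest$ontology_path)) {
    read_obo(manifest$ontology_path)
  }
  thesauri <- read_thesauri(manifest)
  associations <- if (!is.null(manifest$association_path)) {
    read_associations(manifest$association_path)
  } else {
    data.frame(disease_name = character(0), disease_class = character(0),
               gene_symbol = character(0), stringsAsFactors = FALSE)
  }
  mappings <- map_diseases(associations$disease_name, ontology,
                           thesauri = thesauri,
                           ambiguous_floor = manifest$ambiguous_floor)
  network <- assemble_network(gene_edges, ontology, mappings, associations,
                              genes = names(features))
  structure(list(manifest = manifest, features = features, simmat = simmat,
                 gene_edges = gene_edges, ontology = ontology,
                 thesauri = thesauri, associations = associations,
                 mappings = mappings, network = network),
            class = "gdnet_pipeline")
}

#' @export
print.gdnet_pipeline <- function(x, ...) {
  cat("gdnet pipeline result\n")
  cat("  genes:", length(x$features), "| gene edges:", nrow(x$gene_edges),
      "(threshold", x$manifest$threshold, ")\n")
  if (!is.null(x$ontology)) cat("  ontology terms:", length(x$ontology), "\n")
  tiers <- vapply(x$mappings, `[[`, "", "tier")
  cat("  disease names mapped:", sum(tiers != "unmapped"), "of",
      length(tiers), "\n")
  print(x$network)
  invisible(x)
}
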