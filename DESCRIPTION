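Package: gdnet
Title: Extended Gene-Disease Networks with Ontology-Mapped Disease Names and
    Scored Path Retrieval
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds a heterogeneous gene-disease network from three kinds of
    evidence: a gene relation network derived from multi-source feature-set
    overlap, the is-a backbone of a disease ontology, and curated gene-disease
    association records. Free-text disease names are normalized onto ontology
    terms through a four-tier cascade (direct, half-ambiguous, cross-reference,
    ambiguous) driven by a word-weighted name similarity score. On the fused
    network, a seeded bidirectional search retrieves paths between any disease
    and gene under a path-length bound, and each path is scored with a
    confidence that stays strictly positive whenever a path exists. Includes
    readers and writers for the tab-separated and OBO flat-file formats
    involved, and a seeded generator of synthetic fixture bundles with planted
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
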