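Package: gfdnet
Title: Functional Dissimilarity Scoring of Gene Networks with the Gene
    Ontology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Measures the functional dissimilarity of a gene network
    against the Gene Ontology. For every annotated gene the package
    selects, from the gene's candidate GO terms, the annotation that
    makes the whole network most cohesive given its topology; every edge
    is then weighted by a deepest-common-ancestor dissimilarity between
    the selected terms and the network is scored by the average edge
    weight, a value in [0, 1] where 0 means the genes share one common,
    specific function.  Includes readers for OBO ontologies, GAF 2.x and
    TSV annotation files and SIF/edge-list networks, exhaustive,
    branch-and-bound and greedy searches over term assignments, a seeded
    synthetic-data generator for offline testing, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    optparse,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
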