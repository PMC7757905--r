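Package: hgcrd
Title: Local Hypergraph Clustering via Capacity-Releasing Diffusion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Seed-based local clustering for hypergraphs and motif hypergraphs of
    (biological) interaction networks. Implements HG-CRD, a capacity-releasing
    push-relabel flow diffusion that operates directly on hyperedges, together with
    its edge-based ancestor CRD and the motif-adjacency variant CRD-M; motif
    (triangle, directed triad) enumeration and motif adjacency construction;
    conductance and motif-conductance cluster quality metrics; simple hypergraph
    neighborhood baselines; synthetic planted-partition and mixing-parameter
    benchmark generators; and a best-seed / seed-distribution evaluation harness.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    Matrix,
    tibble,
    generics,
    ggplot2,
    methods,
    rlang,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
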