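Package: vulnmap
Title: Molecular and Connectomic Contributions to Cortical Abnormality Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for relating parcellated cortical-abnormality maps to
    local molecular attributes and global connectome architecture.
    Implements multilinear abnormality models with dominance analysis and
    distance-dependent cross-validation, network-spreading statistics and
    epicentre-likelihood mapping, inter-regional disorder-similarity
    analysis, distance-binned group-consensus structural connectomes,
    weighted graph metrics (strength, betweenness, closeness,
    participation coefficient, clustering, mean first passage time), and
    two spatial null models (hemisphere-aware spin permutations and
    degree- and edge-length-preserving network rewiring). A synthetic-data
    module generates spherical parcellations, distance-dependent subject
    connectomes, coupled functional networks, spatially autocorrelated
    molecular maps, and abnormality maps with planted linear or
    network-diffusion structure so every stage can be validated against a
    known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    igraph,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
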