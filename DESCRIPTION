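Package: idionet
Title: Topology-Driven Idiotypic Immune Network Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and topological analysis of binary idiotypic
    (antibody) networks with multilinear n-body mean-field couplings defined
    on the clique complex of the coupling graph. Provides exact
    statistical-mechanics by enumeration (partition function, correlation
    functions, observable sweeps), simplicial homology over GF(2) and the
    rationals, Vietoris-Rips persistent homology of antibody concentration
    data, a Betti-number-driven coupling-inference and adaptation loop, and
    a two-dimensional Z2 Regge-calculus state sum on closed triangulated
    surfaces.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
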