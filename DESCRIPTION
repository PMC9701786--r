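Package: netcongruence
Title: Geometrical Congruence and Greedy Navigability of Complex Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify how closely a network topology follows an
    underlying geometry. Implements the geometrical congruence (GC) measure
    based on the exhaustive enumeration of all topological shortest paths and
    their geometrical projections, with an optimized enumeration algorithm
    combining memoization and source-node prioritization; greedy routing
    (myopic transfer) simulation and the greedy routing efficiency (GRE);
    a nonuniform popularity-similarity optimization (nPSO) generator for
    hyperbolic soft random geometric graphs with tailored communities; and a
    marker pipeline applying GC and navigation efficiency to cohorts of
    weighted brain connectomes, with precision-recall evaluation and
    permutation-based trustworthiness.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    Matrix,
    methods,
    parallel,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
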