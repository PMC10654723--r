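Package: fateSpace
Title: Spatial Analysis of Intermingled Stem-Cell Fate Specification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for asking whether stem-cell fate choices are spatially
    clustered or intermingled in three-dimensional tissue. Provides rule-based
    calling of planarian neoblasts, specialized (fate-committed) neoblasts,
    smedwi-1-low progenitors and mature cells from per-cell transcript counts;
    nearest-neighbor and Voronoi-tessellation neighborhood composition
    statistics with label-permutation nulls; distance measurements from
    classified cells to mature tissues, including an obstacle-aware border
    routing around the pharyngeal cavity; and a synthetic 3D tissue generator
    (hard-core cell fields, intermingled / clustered / target-biased labeling
    regimes, calibrated Poisson transcript emission) so the whole pipeline is
    testable without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml,
    withr
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
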