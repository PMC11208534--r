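Package: gridtorus
Title: Toroidal Topology of Grid Cell Population Activity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Covariate-free detection of neural ensembles and of the
    toroidal structure of their population state space. Converts spike
    trains or calcium events to smoothed firing rates, clusters neurons
    into putative grid modules from time-lagged cross-correlations,
    reduces the population point cloud by radial and fuzzy downsampling,
    computes Vietoris-Rips persistent cohomology with finite-field
    coefficients and shuffle-based significance, turns persistent
    1-cocycles into circle-valued coordinates on the ensemble state
    space, builds toroidal rate maps, classifies tori as hexagonal or
    square against analytic heat-kernel models, and aligns toroidal
    representations across sessions. Includes three continuous attractor
    network simulators of grid modules as a synthetic data source.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    graphics,
    utils,
    Matrix,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
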