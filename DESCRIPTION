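Package: enoser
Title: Electronic-Nose Temperature-Sweep Analysis for Skin Odor Classification
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Pipeline for analysing metal-oxide gas-sensor conductance
    sweeps recorded on the human skin surface with an electronic nose:
    a seeded synthetic cohort generator, interpolation and averaging to
    representative conductance-versus-temperature curves, time-domain
    index extraction (areas, windowed subareas, steepest slopes),
    frequency-domain indices from a continuous Daubechies wavelet
    transform summarized into scale packages and temperature windows,
    and four cross-validated classification procedures (PCA with
    linear/quadratic discriminant analysis, stepwise discriminant
    analysis, and an RBF-kernel support vector machine with grid search
    and greedy forward index selection).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
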