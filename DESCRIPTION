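Package: rehabdst
Title: Decision-Support Tools for Robotic Rehabilitation Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Systematic data management for kinematic time series recorded by
    upper-limb rehabilitation robots during serious-game therapy, and two
    decision-support tools built on the harmonized series: a per-time-step
    recurrent predictor of discharge clinical scores (ARAT, FMA, Motricity
    Index) and a next-session recommender of robot difficulty parameters
    (stiffness, weight, viscosity). Includes per-round log ingestion with
    automode exclusion and feature-mutuality filtering, a 36-column feature
    schema with seven time-related features, four invertible normalization
    schemes, padding/shrinking of variable-length series to a fixed 64-point
    grid, a stacked-LSTM engine written in C++, random-forest baselines,
    patient-level cross-validation, permutation feature importance, and a
    seeded synthetic-cohort generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    ranger,
    stats,
    utils,
    graphics
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
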