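Package: flowssm
Title: State-Space and Dynamic Linear Models for Flow-Ecology Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing flow-ecology relationships in long-term
    fish monitoring data. Implements catch-per-unit-effort (CPUE)
    preprocessing (completeness filtering, log transformation, outlier
    interpolation, seasonal-window annual aggregation), a Gaussian linear
    state-space engine with missing-data Kalman filtering and smoothing and
    maximum-likelihood estimation (EM and BFGS), multivariate autoregressive
    state-space (MARSS) comparison of competing spatial population
    structures via AICc, time-averaged flow-covariate effects, dynamic
    linear models (DLMs) with random-walk intercepts and slopes for
    time-varying flow effects, robust trend descriptives (Theil-Sen,
    coefficient of variation, period-wise index regressions), and a
    comparison of time-averaged versus time-varying flow effects. A
    seed-deterministic synthetic-data generator emulates multi-station,
    two-gear estuarine trawl monitoring for validation by simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    numDeriv,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
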