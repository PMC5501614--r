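Package: fadfit
Title: Simple and Complex Contagion Models for Online Behavioural Fads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Fits mechanistic contagion models to weekly search-interest time
    series of briefly popular online behaviours ('fads'). Implements a
    threshold-based complex contagion model and a mass-action simple contagion
    model as SIJR compartmental systems, an exact event-driven stochastic
    simulator of the underlying Markov chain, maximum-likelihood fitting under
    a Gamma observation model with amplitude, time-shift and shape nuisance
    parameters, AIC-based model comparison with evidence grading,
    two-sub-population extensions for bimodal series, out-of-sample
    forecasting with plug-in prediction intervals, and a synthetic-data
    generator emulating percent-of-peak weekly series.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    purrr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
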