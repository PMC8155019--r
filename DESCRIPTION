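Package: polburst
Title: Bursting Kinetics and Phosphorylation Dynamics of RNA Polymerase II
    at a Single Gene
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to model and analyse RNA polymerase II (RNAP2)
    transcriptional bursting at a single reporter gene from multi-channel
    fluorescence fluctuation time series. Provides the linear moment
    equations of a bursting model (steady-state means, Lyapunov
    covariances, lagged auto- and cross-covariances), replica-averaged
    correlation-function estimators with shot-noise correction, composite
    maximum-likelihood parameter inference with BIC model selection, an
    exact Gillespie simulator with simulated ChIP occupancy profiles and
    inhibitor perturbations, trace-level analyses (minima alignment,
    centroid distance statistics, run-off decay fitting), and a synthetic
    experiment generator so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    pracma,
    zoo,
    minpack.lm,
    jsonlite,
    yaml,
    readr
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    Matrix
Config/testthat/edition: 3
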