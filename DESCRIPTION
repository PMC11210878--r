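Package: thresholdtx
Title: Threshold-Aware Stochastic Optimal Control for Adaptive Cancer Therapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes adaptive drug-dosing policies for stochastically evolving
    heterogeneous tumors. Given a controlled drift-diffusion model of tumor
    composition and size, the package solves the stationary Hamilton-Jacobi-
    Bellman equation of the deterministic control problem (minimal cumulative
    treatment cost to stabilization or eradication) and the threshold-aware
    parabolic Hamilton-Jacobi-Bellman equation whose solution is the maximal
    probability of reaching the therapy goal without the cumulative cost
    exceeding a prescribed budget. Bang-bang feedback policies are extracted
    for all budget levels simultaneously and validated by Euler-Maruyama
    Monte-Carlo simulation of therapy courses, with empirical cost CDFs and
    policy comparisons returned as tidy tibbles. Two models are included: an
    evolutionary-game (replicator) competition of glycolytic, defector and
    VEGF-overproducing cancer cells, and a sensitive-resistant logistic
    competition model of drug response.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    ggplot2,
    rlang,
    generics,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
SystemRequirements: C++17
Config/testthat/edition: 3
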