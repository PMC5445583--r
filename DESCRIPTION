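Package: woundabc
Title: Approximate Bayesian Computation for Lattice Models of Wound-Healing Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Continuous-time lattice exclusion-process simulation of
    wound-healing (scratch) assays with two cell-cell adhesion models,
    summary statistics (average horizontal displacement, column density
    profile, and a volume-exclusion-normalised pair-correlation function),
    approximate Bayesian computation (rejection and MCMC) for inferring
    motility and adhesion parameters, and Kullback-Leibler-divergence-based
    comparison of experimental designs (replicate number versus domain
    size). The Gillespie event loop is implemented in C++ for speed; all
    user-facing functions return tibbles.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Matrix
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
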