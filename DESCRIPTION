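Package: kuranet
Title: Synchronization Criticality of the Kuramoto Model on Large Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulation and scaling analysis of the weighted Kuramoto model on
    large sparse networks: small-world lattice and hierarchical-modular
    connectome-like graph generators, incoming-weight normalization and
    inhibitory-link perturbations, a fast fixed-step fourth-order Runge-Kutta
    integrator with exponentially spaced sampling, first-passage
    (de)synchronization duration statistics with power-law-binned histograms,
    and effective-exponent machinery for locating the critical coupling and
    estimating the dynamical exponents of order-parameter growth and decay.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    igraph,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    broom
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
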