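Package: clutchsim
Title: Stochastic Motor-Clutch Simulation of Focal Adhesion Mechanosensing
    Under Residual Strain
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Gillespie (first-reaction) stochastic simulation of the motor-clutch
    model of cell-substrate force transmission, extended with an orthogonal
    elastic spring that stores extracellular-matrix residual strain. Provides
    the force laws (Bell slip-bond kinetics, Hookean clutch springs, nonlinear
    two-spring substrate anchorage, Hill force-velocity relation), a compiled
    event-driven simulation engine, parameter sweeps over the clutch number
    with cubic-spline optimum detection, strain-response curves with secant
    rates of change, and tidy result objects with plotting methods.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    readr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
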