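Package: tetherflow
Title: Brownian Dynamics of Surface-Tethered DNA in Shear Flow with
    Crowding-Induced Attraction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates a surface-tethered bead-spring DNA chain in laminar
    shear flow by overdamped Brownian dynamics in reduced units, including a
    short-ranged attractive pair interaction between chain segments that
    models the depletion effect of the crowding agent polyethylene glycol
    (PEG).  Provides steady-state extension and fluctuation observables,
    relaxation-time estimation from end-vector autocorrelation and
    relaxation-to-equilibrium protocols, flow-cell hydrodynamics helpers,
    viscosity-table reduction, and the viscosity-to-Weissenberg-number
    calibration pipeline that links simulations to single-molecule DNA
    flow-stretching measurements.  Includes a synthetic generator for
    per-molecule quantum-dot trace statistics and a small command-line
    interface.
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
    rlang,
    readr,
    jsonlite,
    ggplot2,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
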