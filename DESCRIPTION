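Package: gaitdyn
Title: Synthetic IMU Gait Trials and Nonlinear Dynamics of Human Walking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and nonlinear time-series analysis of overground
    walking recorded with body-worn inertial sensors. Generates four-minute
    synthetic walking trials with known ground truth (gait events, stride
    lengths and times with tunable long-range correlation, left-right phase
    offset, sensor drift), detects heel strikes and toe offs, derives the
    standard 26-column spatiotemporal gait parameter table, and runs three
    validation analyses: continuous relative phase between left and right
    segment pitch angles via the Hilbert analytic signal, the largest
    Lyapunov exponent of segment angle dynamics by Wolf's algorithm with
    AMI/FNN delay embedding, and Bayesian estimation of the Hurst exponent
    of stride series under a fractional Gaussian noise model, with shuffled
    surrogates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    deSolve,
    jsonlite,
    optparse
Config/testthat/edition: 3
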