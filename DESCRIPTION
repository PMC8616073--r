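Package: itesim
Title: Artificial Immune-Tumor Ecosystem Simulation of Thermoradiotherapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic simulation of an artificial immune-tumor ecosystem
    under fractionated radiotherapy combined with mild hyperthermia. Tumor
    sub-clones on a mutation tree, host tissue and necrotic cell compartments
    are coupled through ordinary differential equations; the adaptive immune
    response is represented by a continuously trained perceptron comparing a
    danger signal from immune-stimulatory dying cells with antigen-pattern
    signals, driving effector-cell production. Radiation cell kill follows a
    dynamic linear-quadratic law based on a transient biological dose
    equivalent; hyperthermia acts through fixed radio-sensitization factors
    and first-order perfusion and immune-stimulation kinetics. The package
    provides fractionation and hyperthermia protocol presets, a fixed-step
    Runge-Kutta engine in compiled code, tumor-control-probability (TCP)
    evaluation, protocol grids, tidy accessors and plotting helpers.
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
    ggplot2,
    generics,
    yaml,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse,
    withr
Config/testthat/edition: 3
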