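Package: scpw
Title: Analysis Toolkit for the Super Compact Pairwise SIS Network Epidemic Model
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools for the super compact pairwise (SCPW) approximation of
    susceptible-infectious-susceptible (SIS) epidemics on networks with
    heterogeneous degree. Computes degree-distribution moments and the
    derived closure constants, evaluates and integrates the dimensional,
    nondimensional and reduced model systems, derives the epidemic
    threshold and disease-free-equilibrium stability, solves the
    steady-state polynomial system for the exact endemic equilibrium with
    continuation over a transmission-ratio grid, evaluates near- and
    far-from-threshold perturbation approximations of endemic prevalence,
    and provides closed-form sensitivities of prevalence to the first
    three degree-distribution moments with feasibility masking. Results
    are returned as tibbles with broom-style tidy()/glance() and ggplot2
    autoplot() methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
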