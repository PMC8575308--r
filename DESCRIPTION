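Package: metaglv
Title: Spatial Generalised Lotka-Volterra Metacommunity Simulation
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of random generalised Lotka-Volterra
    (GLV) communities coupled by nearest-neighbour dispersal on periodic
    lattices (a ring in one dimension, a torus in two).  Provides seeded
    generators for random interaction matrices and per-species diffusion
    rates, a compiled adaptive Runge-Kutta integrator for the spatial and
    non-spatial GLV equations, measurement routines for oscillation
    classification, Fourier phase-shift synchronisation, amplitudes and
    diversity, locators for the feasibility and stability boundaries of
    the non-spatial system, and a reproducible parameter-sweep runner over
    the (diffusion magnitude x interaction-strength standard deviation)
    plane.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
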