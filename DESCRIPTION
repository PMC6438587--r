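Package: ringwander
Title: Stochastic Wandering Bumps and Stimulus-Dependent Variability in
    Ring Attractor Networks
Version: 0.1.0
Authors@R:
    person("Ring", "Wander", email = "maintainer@ringwander.org",
           role = c("aut", "cre"))
Description: Tools for analyzing stimulus-dependent neural variability in
    one or two coupled ring attractor networks modeled as stochastic
    neural fields.  Solves for stationary activity bumps and their linear
    stability, reduces the field dynamics perturbatively to stochastic
    phase equations for the wandering bump (drift amplitude, inter-network
    coupling functions, and diffusion coefficients), and evaluates the
    analytic steady-state circular statistics: von Mises phase densities,
    tuning of response means and variances, the bivariate cosine-model
    von Mises distribution for vertically coupled layers, and the
    generalized stationary density for horizontally coupled hypercolumns.
    Includes Euler-Maruyama simulators (in C++) for the full neural field
    and the reduced phase equations, so that simulation and analytics
    cross-validate each other, plus a command-line interface for running
    the standard experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
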