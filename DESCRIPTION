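Package: ecoevosep
Title: Separating Ecological and Evolutionary Time Scales by
    Weak-Selection Perturbation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for frequency- and density-dependent population
    dynamics in the weak-selection regime.  Birth and death rates are
    factorised into a shared baseline, an order-epsilon genotype-specific
    perturbation, and density-dependent factors; the package provides the
    change of variables from genotype abundances to frequencies plus
    total density, the coupled full dynamics, zeroth- and first-order
    inner (ecological) and outer (evolutionary) approximations, matched
    asymptotic composite solutions, and error-scaling experiments that
    estimate the convergence order of each approximation from log-log
    slopes.  Two models are built in: a public-goods producer/free-rider
    game under logistic growth and a Lotka-Volterra system of one prey
    and two competing predators.  A thin command-line interface drives
    simulations and error sweeps from JSON configuration files.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
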