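Package: cfcsim
Title: Stochastic Simulation of Thin-Filament Regulation by a Continuous
    Flexible Tropomyosin-Troponin Chain
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models calcium regulation of myosin-S1 binding to actin
    filaments with a continuous flexible tropomyosin-troponin chain
    confined in an azimuthal harmonic well on the actin surface. Computes
    the mean chain angle and its thermal fluctuations for arbitrary
    troponin-I and strong-myosin pinning configurations by constrained
    minimisation of the discretized chain energy, converts the chain state
    into chain-regulated binding and isomerization rates, and runs
    fixed-timestep kinetic Monte Carlo simulations of filament ensembles
    that reproduce stopped-flow style binding transients. Includes the
    single-parameter calcium-dependence fitting procedure for the
    troponin-I detachment rate, Hill analysis of the resulting K_B-pCa
    relationship, synthetic-transient generation, cluster statistics, and
    command-line entry points.
License: MIT
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    minpack.lm,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    deSolve,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
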