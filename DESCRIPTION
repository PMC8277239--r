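Package: gammaprc
Title: Macroscopic Phase-Response Curves and Entrainment of Gamma Rhythms in
    Heterogeneous Spiking Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for studying how neuronal
    heterogeneity shapes the macroscopic phase response and entrainment of
    ING and PING gamma rhythms. Provides event-handling simulators for
    all-to-all networks of leaky (IF) and quadratic (QIF) integrate-and-fire
    neurons with delayed double-exponential synapses, measurement of the
    finite-amplitude macroscopic phase-response curve (fmPRC), iterated
    one-cycle phase maps with fixed-point and bifurcation analysis, forced
    ("clock"-driven) simulations with synchronization-type classification,
    and the exact mean-field reduction of QIF networks with adjoint-based
    infinitesimal macroscopic PRCs (imPRC).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    deSolve,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
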