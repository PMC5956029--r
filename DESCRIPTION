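Package: isingadapt
Title: Driving Ising Neural Networks to Criticality by Correlation-Invariant
    Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to adapt arbitrary Ising (Boltzmann-machine) neural
    networks towards a critical point by maintaining a distribution of
    pairwise correlations harvested from a two-dimensional lattice Ising
    model at its exact critical coupling. Provides Glauber-dynamics Monte
    Carlo and exact enumeration for small systems, the rank-aligned
    inverse-Ising (Boltzmann) learning rule for isolated and embodied
    networks, implementations of the Mountain Car and Acrobot control
    benchmarks with binary sensor/motor coding, and a diagnostics suite
    for criticality signatures: heat-capacity divergence across an
    inverse-temperature sweep, Zipf rank scaling of activity states, and
    behavioural susceptibility of embodied agents.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
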