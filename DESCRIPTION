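Package: thetanet
Title: Chaotic Balanced Theta-Neuron Networks, Spike-Word Noise Entropy,
    and Kolmogorov-Sinai Bounds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates sparse balanced excitatory-inhibitory networks of
    theta (quadratic integrate-and-fire phase) neurons driven by quenched
    realizations of white-noise input, treated as a random dynamical system:
    many initial conditions, one frozen input. Provides direct spike-word
    noise-entropy estimation with extensive-trend extrapolation,
    cross-trial noise correlations, homogeneous and inhomogeneous Poisson
    surrogate controls, Lyapunov spectra of the driven network with the
    Kolmogorov-Sinai upper bound on network spike-pattern entropy, and
    checks of the state-space partition that links phases to binary spike
    words, including a piecewise model variant for which the partition
    spiking rule is exact.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    methods,
    stats,
    utils,
    grDevices
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
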