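Package: rsrp
Title: Reward-Optimized Stochastic Release Plasticity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Learning rule that models each synapse as a Bernoulli release
    distribution and adapts release probabilities by natural-gradient ascent
    on a global reward signal. Provides the plasticity rule with clipping,
    the score-function gradient estimator and its Fisher preconditioning,
    centered-rank and zero-mean reward regularization, excitatory-inhibitory
    balanced feedforward and recurrent leaky integrate-and-fire spiking
    networks (with a frozen-reservoir variant), a bundled cart-pole
    simulator, sparse-reward classification training on synthetic digit and
    cluster datasets, and an exact enumeration oracle for gradient checks.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
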