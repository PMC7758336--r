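Package: twopathway
Title: Fast and Slow Synaptic Learning in Parallel Pathways
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulator and semi-analytic theory for a two-pathway model of
    synaptic learning, in which a downstream readout population receives one
    input pathway trained by fast supervised (or reinforcement) learning and a
    second pathway trained by slow Hebbian plasticity with weight decay.
    Implements the margin perceptron with sequential and cycled training,
    Monte-Carlo and drift-diffusion forgetting curves, repetition-dependent
    retention, input alignment and control-transfer analyses, lesion and noise
    perturbation tests, REINFORCE policy-gradient learning with habit
    formation, and a center-out reaching task with minimum-jerk target
    trajectories, together with a reproducible experiment runner.
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
    optparse
Config/testthat/edition: 3
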