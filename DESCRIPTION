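Package: adexnet
Title: Whole-Brain Networks of Adaptive Exponential Mean-Field Models
Version: 0.1.0
Authors@R:
    person("adexnet", "maintainers", email = "adexnet@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis of whole-brain networks of second-order
    adaptive exponential (AdEx) integrate-and-fire mean-field models. Each
    cortical region is a seven-variable neural-mass node (excitatory and
    inhibitory population rates, their covariances, and adaptation currents)
    coupled through a structural connectome with axonal conduction delays,
    driven by an Ornstein-Uhlenbeck process and integrated with a stochastic
    Heun scheme. Includes a synthetic connectome generator, detection of
    paroxysmal (epileptic-like) fixed points, a feature-extraction pipeline
    (firing-rate statistics, Up-state durations, spectral peaks, functional
    connectivity and its correlation with structural connectivity),
    constrained parameter-grid sweeps with checkpointing, and K-means
    classification of adaptation-dependent functional-connectivity traces.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    parallel,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
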