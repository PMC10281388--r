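Package: crossim
Title: Cognitive Simulation of Driver-Pedestrian Road-Crossing Interaction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An agent-based simulator of driver-pedestrian road-crossing
    interactions built from integrated computational-psychology components:
    motor-primitive locomotion control, noisy perception with Kalman-filter
    Bayesian estimation of the other agent's motion, theory-of-mind estimation
    of the other agent's intended access order from observed motion and from
    value rationality, short-term payoff and affordance-based long-term
    valuation of candidate actions, and threshold-gated evidence-accumulation
    action selection. Includes scenario factories for phenomenon-based model
    selection (priority assertion, short-stopping, yield and gap acceptance
    hesitation, early yield acceptance), deterministic and stochastic
    parameter-grid screens, and simulated replications of two controlled
    crossing experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
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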