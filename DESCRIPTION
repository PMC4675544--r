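Package: locustmarch
Title: One-Dimensional Self-Propelled-Particle Models of Locust Marching
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Agent-based simulators for the family of one-dimensional
    self-propelled-particle models used to describe marching locust nymphs
    in ring-shaped arenas (the Czirok alignment model and its continuous
    form, the individual-choice model, the Buhl model with a self-excluded
    local average, a one-dimensional three-zone model, an intermittent
    pause-and-go model with movement-gated alignment, and the
    escape-and-pursuit social-force model), together with the
    coarse-graining machinery used to analyse them: the directional order
    parameter, metastable-state labelling and switching statistics,
    waiting-time analysis, and binned estimation of the effective drift
    and diffusion functions of the order parameter with fixed-point
    classification. Includes a synthetic stochastic-differential-equation
    generator for validating the estimators, reproducible parameter scans,
    and plain-text input/output for trajectories and order-parameter
    series.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
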