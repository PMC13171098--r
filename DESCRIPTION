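Package: motorsavings
Title: Context-Free Savings in Recurrent Network Models of Force-Field
    Adaptation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Trains gated recurrent unit (GRU) controllers with delayed
    visual and proprioceptive feedback to drive a muscle-actuated planar
    two-joint arm, exposes them to a velocity-dependent curl force field
    in a null-field / force-field / washout / re-exposure protocol, and
    quantifies behavioural savings together with its neural-geometry
    correlates: a force-predictive preparatory subspace found by targeted
    dimensionality reduction, a phase-dependent uniform shift of
    preparatory activity, and causal hidden-state perturbations along
    that shift.  The differentiable simulation engine (recurrent
    controller, simplified Hill-type musculoskeletal plant, and
    backpropagation through time) is implemented in compiled code.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    minpack.lm,
    stats,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    jsonlite,
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
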