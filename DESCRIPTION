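Package: rotdyn
Title: Rotational Population Dynamics in Feedback-Driven Neural Controllers of a Two-Link Arm
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains two-layer leaky recurrent (and feedforward) neural
    controllers of a planar two-joint, six-muscle arm with delayed sensory
    feedback on posture-perturbation, delayed center-out reach and
    constant-velocity tracking tasks, and quantifies rotational population
    dynamics in the resulting activity. Provides jPCA-style analysis
    (soft normalization, cross-condition mean subtraction, PCA reduction,
    skew-symmetric and unconstrained linear dynamical fits, rotation-plane
    frequencies and variance accounted for), tensor-maximum-entropy
    surrogate nulls, down-sampling controls, sensory-feedback decoding of
    rotation planes, and synthetic population generators with planted
    rotational structure for validation. Backpropagation through time with
    an analytic plant Jacobian is implemented in vectorized R.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
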