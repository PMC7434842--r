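Package: tendonstrain
Title: Real-Time Multiscale Estimation of Localized Achilles Tendon Strain
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: EMG-informed Hill-type modelling of the triceps surae coupled to a
    personalized finite-element model of the free Achilles tendon.  Muscle
    forces estimated from joint angles and EMG envelopes drive a fast spline
    surrogate of the finite-element model, yielding per-Gauss-point
    fiber-aligned strain fields frame by frame at motion-capture rates.
    Includes a seeded synthetic-subject generator (profile, tendon geometry,
    isometric force-elongation series, dynamic trials with ground-truth
    parameters), a C1-continuous piecewise quadratic-linear tendon
    force-strain curve fit, inverse calibration of the neuromusculoskeletal
    and constitutive parameters, leave-one-out surrogate validation, and a
    causal streaming pipeline with latency instrumentation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    mixOmics,
    signal,
    splines,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
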