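Package: armfji
Title: Involuntary Arm Impedance Estimation via Feedback Jerk Isolation
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Estimation of the involuntary impedance components (base inertial
    parameters, joint damping, and joint stiffness) of a planar two-joint arm
    from force-perturbed movements. Implements feedback jerk isolation via
    energy-spectral-density based cutoff selection and zero-phase high-pass
    filtering of endpoint jerk, a two-stage estimation protocol (static-task
    linear least squares for the base inertial parameters, dynamic-task
    Cholesky-constrained nonlinear least squares for damping and stiffness),
    two reference estimators for comparison, and a neuromechanical simulator
    of a two-link six-muscle arm coupled to an admittance-controlled
    manipulandum for validation on synthetic data with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    optparse
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
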