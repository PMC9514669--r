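Package: ocdspe
Title: Optimally Controlled Dynamical State and Parameter Estimation for
    Nonlinear ODE Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Joint inference of hidden dynamical states and fixed parameters
    in nonlinear and chaotic ordinary differential equation models, with an
    emphasis on conductance-based neuron models observed sparsely and with
    substantial measurement noise.  Implements the OC-DSPE estimator, in
    which time-dependent nudging controls are eliminated via the Pontryagin
    minimum principle and the resulting estimation dynamics for states and
    conjugate momenta are enforced as annealed Hermite-Simpson collocation
    constraints, alongside three baselines: fixed-gain nudging, dynamical
    state and parameter estimation (DSPE), and constrained least squares
    (variational annealing).  Includes built-in Lorenz96 and Morris-Lecar
    models and a twin-experiment harness for synthetic-data validation.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    deSolve,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
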