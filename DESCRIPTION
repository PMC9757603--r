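Package: ikweights
Title: Identification of Inverse-Kinematics Weights for Inter-Joint
    Coordination Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Model-based quantification of inter-joint coordination in
    kinematically redundant systems. Joint and end-effector velocity
    recordings are explained through a weighted pseudo-inverse of the
    Jacobian matrix; the diagonal weight matrix is identified from data by
    an iterative, box-constrained quadratic-programming estimator. Includes
    task/null-space velocity decomposition, contribution coefficients,
    synthetic benchmark generators (random redundant chains, a two-joint
    prismatic chain with goal switching, an assistive virtual-elbow
    scenario), cohort-level estimation workflows with a paired Hotelling
    T-squared condition contrast, and a plain-text interchange format for
    kinematic trials.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
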