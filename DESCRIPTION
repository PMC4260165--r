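Package: doublecv
Title: Repeated Double Cross-Validation for Regression Under Model
    Uncertainty
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for repeated double (nested) cross-validation of
    regression models under model uncertainty, as used in QSAR and related
    descriptor-based modelling.  The inner loop selects a model (tabu-search
    variable-subset selection with multiple linear regression or principal
    component regression, Lasso penalty selection, or simulated-annealing
    k-nearest-neighbour descriptor selection); the outer loop assesses the
    selected model on held-out test objects.  Includes a full bias-variance
    decomposition of coefficient, model and prediction errors against a known
    population, a synthetic-data generator for AR(1)-correlated Gaussian
    designs with sparse linear signals, descriptor-table prefiltering
    (variance and correlation filters, CAR-score preselection), and a study
    driver that runs the simulation grid at configurable scale.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    glmnet,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
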