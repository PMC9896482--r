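Package: nucleokin
Title: Stochastic Primary Nucleation Kinetics and Hydrodynamic Scale-Up
    Correlations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing stochastic primary nucleation in stirred
    crystallizers. Fits the Poisson (shifted-exponential) induction-time
    distribution model to isothermal induction-time series by direct
    nonlinear least squares, maximum likelihood, and bootstrap resampling;
    benchmarks the estimators on synthetic data; computes classical
    scale-up quantities (Reynolds number, impeller tip speed, specific
    power input) and ingests CFD-derived hydrodynamic feature tables;
    trains and validates regression models correlating nucleation rate and
    growth time with vessel hydrodynamics, with leave-one-out validation
    and error-band performance metrics; and ensembles the models to
    predict induction-time probability distributions with Shapley-value
    feature attribution.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    glmnet,
    randomForest,
    xgboost,
    caret,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
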