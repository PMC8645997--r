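Package: polyBpopPK
Title: Population Pharmacokinetics and Dosing Simulation of Polymyxin B in
    Obese Adults
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-compartment intravenous-infusion population pharmacokinetic
    pipeline for polymyxin B in obese adults: closed-form concentration and AUC
    computation under arbitrary piecewise-constant infusion schedules, synthetic
    cohort generation matching the study design (rich and sparse steady-state
    sampling with lognormal inter-individual variability, proportional residual
    error and LLOQ censoring), FOCE-with-interaction nonlinear mixed-effects
    estimation with empirical-Bayes etas, shrinkage, stepwise covariate
    selection and nonparametric bootstrap, goodness-of-fit residuals and a
    prediction-corrected visual predictive check, and Monte Carlo evaluation of
    fixed and bodyweight-based dosing regimens against AUC exposure targets and
    AUC/MIC probability-of-target-attainment criteria.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    deSolve,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
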