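Package: transitpk
Title: Population Pharmacokinetics with Transit-Compartment Absorption
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Nonlinear mixed-effects population pharmacokinetic modelling
    built around the two-compartment transit-absorption model used for oral
    imatinib. Provides a structural-model ladder (one- to three-compartment
    disposition with first-order, lagged, zero-order, double-peak and
    transit-compartment absorption), FOCE-with-interaction estimation with
    empirical Bayes (MAP) individual estimates, shrinkage and conditional
    weighted residuals, likelihood-ratio/AIC model selection with stepwise
    covariate analysis, non-compartmental analysis, visual predictive checks
    and nonparametric bootstrap, MAP Bayesian application of a fixed
    population model to steady-state therapeutic drug monitoring data, and
    synthetic cohort generators for healthy-volunteer and patient designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    knitr
Config/testthat/edition: 3
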