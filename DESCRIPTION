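Package: tdauc
Title: Time-Dependent ROC Curves and AUC for Censored Event-Time Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimators of time-dependent ROC curves and AUC for
    right-censored event-time data with a scalar baseline marker or a
    longitudinally measured biomarker. Implements the
    cumulative/dynamic family (naive, conditional Kaplan-Meier,
    nearest-neighbour bivariate survival, Kaplan-Meier-like recursion,
    Cox model based, marginal and marker-conditional inverse probability
    of censoring weighting, interval-weighted AUC, and conditional
    absolute-risk plug-ins under Cox, Aalen additive and conditional
    Kaplan-Meier models), the incident/dynamic family (riskset Cox
    regression with time-varying coefficient smoothing, weighted mean
    rank, fractional-polynomial pseudo partial-likelihood) with the
    concordance summary, and incident/static and longitudinal-marker
    methods (extended Cox riskset with static controls, landmark
    last-value nearest-neighbour estimation, induced binormal ROC from
    case/control linear mixed-effects models, and ROC-GLM with probit
    link). Includes subject-level bootstrap confidence intervals,
    synthetic-cohort generators with quadrature oracles for the true
    cumulative/dynamic and incident/dynamic AUC, delimited-text readers
    and writers, and a command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    survival,
    MASS,
    lme4,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
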