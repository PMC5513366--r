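Package: psadyn
Title: Individual Dynamic Prediction of Death Risk from Nonlinear PSA Kinetics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Nonlinear joint modelling of prostate-specific antigen (PSA)
    kinetics and survival in metastatic castration-resistant prostate cancer.
    PSA trajectories follow a biexponential treatment-escape model with
    log-normal and logit-normal random effects; the hazard of death is a
    Weibull baseline modulated by a function of the current (true) PSA level,
    its slope or its cumulative area. The package draws subject-level random
    effects from their posterior distribution given PSA measurements up to a
    landmark time, turns the draws into Monte Carlo medians and 95% prediction
    intervals for future PSA and for the conditional probability of death over
    a horizon, and evaluates the predictions with time-dependent AUC, Brier
    score and scaled Brier score under inverse-probability-of-censoring
    weighting. A cohort simulator makes the whole pipeline reproducible
    without access to trial data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    pracma,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    deSolve
Config/testthat/edition: 3
RoxygenNote: 7.3.3
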