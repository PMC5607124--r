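Package: diurnalfatigue
Title: Within-Session Mental Fatigue and Time-of-Day Effects in Learning-Session Logs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for analysing timestamped learning-session event logs for
    within-session mental fatigue and diurnal (time-of-day) effects. Provides a
    session-log data model with screening and timezone localisation, a synthetic
    cohort generator with fully exposed ground truth for parameter-recovery
    testing, multilevel quadratic fatigue-curve fitting with AIC model
    comparison, harmonic (cosinor) regression of half-hour binned daily metrics
    with WAIC model selection and frozen-model out-of-sample RMSE replication,
    negative log-likelihood scoring of competing theoretical daily-behaviour
    curves, an exploratory moderation analysis of per-session fatigue
    coefficients by time of day, a population-level self-control depletion
    simulator, and an end-to-end two-cohort study pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    sandwich,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
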