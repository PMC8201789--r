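Package: critspeed
Title: Critical Speed Estimation from Exhaustive Run Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation of critical speed (CS) and related power-duration
    parameters from treadmill time-to-exhaustion trials. Implements the
    two-parameter hyperbolic, three-parameter, and three-parameter
    exponential speed-duration models in two mathematically equivalent
    formulations (time as a function of speed and distance as a function
    of speed), fitted by weighted nonlinear least squares with
    inverse-variance weights and Levenberg-Marquardt minimisation.
    Provides fit-quality metrics (confidence intervals, combined percent
    standard error of estimate, AIC, heteroscedasticity diagnostics),
    mapping of CS onto incremental-test physiology (oxygen uptake at CS,
    percent of peak speed), cohort-level linear mixed models with
    variance-explained and intraclass-correlation summaries, log-scale
    correlation utilities, and a seeded synthetic-cohort generator for
    recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    lme4,
    lmerTest,
    emmeans,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
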