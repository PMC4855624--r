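Package: exgstress
Title: Ex-Gaussian Reaction-Time Predictors of Cardiovascular Stress Reactivity and Recovery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for linking ex-Gaussian reaction-time parameters (mu, sigma, tau)
    to cardiovascular reactivity to, and recovery from, acute mental stress.
    Provides trial-level reaction-time cleaning (correct-trial, anticipatory and
    4-SD outlier filters), maximum-likelihood ex-Gaussian fitting, time-domain
    heart-rate-variability (r-MSSD) and period summaries, reactivity/recovery
    change scores, one-way repeated-measures ANOVA with Greenhouse-Geisser
    correction, an SMDM robust linear-regression estimator (S-, M-, design-adaptive
    scale and final M-steps with 95% normal-error efficiency) with robust standard
    errors and an unweighted R-squared, and a seeded synthetic-cohort generator so
    the full pipeline can be exercised and validated without access to human data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
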