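Package: jmsim
Title: Simulation-Based Robustness Assessment of Joint Models and
    Time-Varying Covariate Cox Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to study how well the association between a longitudinal
    biomarker and a time-to-event endpoint is recovered by the time-varying
    covariate Cox model (last observation carried forward) and by the
    shared-random-effects joint model. Provides a synthetic-cohort generator
    (polynomial marker trajectories with normal or non-normal random
    effects, Gaussian measurement error, Weibull or non-monotonic baseline
    hazards, uniform plus administrative censoring), from-scratch maximum
    likelihood fitting of the counting-process Cox partial likelihood and of
    the joint model with constant, Weibull or B-spline baseline hazards
    (pseudo-adaptive Gauss-Hermite integration over random effects), a
    two-stage mixed-model-then-Cox estimator, and a Monte-Carlo harness
    reporting bias, empirical and asymptotic standard errors, coverage and
    mean squared error under a set of misspecification scenarios.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    lme4,
    pracma,
    Rcpp,
    jsonlite,
    yaml,
    splines,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    survival,
    withr
Config/testthat/edition: 3
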