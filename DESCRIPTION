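Package: omtkit
Title: Simulation and Analysis Pipeline for the 'What Was Where?' Visuospatial Memory Task
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for delayed-reproduction ("What was where?") visuospatial
    short-term memory experiments in clinical cohorts. Provides a generative
    simulator of task sessions and multi-group (healthy control, subjective
    cognitive decline, mild cognitive impairment, Alzheimer's dementia)
    cohorts with latent-severity-linked covariates; the four basic
    performance metrics (identification accuracy, absolute localization
    error, identification and localization times); a permutation-based
    mixture-model decomposition of localization responses into target
    detection, misbinding, guessing and imprecision; covariate-adjusted
    group comparisons with Holm-corrected post hoc contrasts, repeated
    measures set-size-by-delay ANOVAs, longitudinal group-by-session models,
    decline-prediction regressions and tests for comparing dependent
    overlapping correlations; and cross-validated linear support vector
    machine classification with DeLong comparisons of correlated ROC curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    car,
    emmeans,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
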