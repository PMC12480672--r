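Package: copdvoice
Title: Speech, Heart-Rate-Variability and Activity Biomarkers for Daily COPD Monitoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for free-living monitoring of chronic obstructive
    pulmonary disease (COPD) from wearable data streams. Extracts phonation,
    prosodic and syllabic-nuclei features from daily speech audio, time-domain
    heart-rate-variability metrics (mean NN, SDNN, pNN20) from 1-Hz wearable
    heart rate, and daily step counts; scores the London COPD cohort daily
    symptom questionnaire and labels exacerbation episodes; and links features
    to outcomes with linear and logistic mixed-effects models, including
    variance-inflation-factor pruning, interaction models and moderation
    analysis stratified by physiological covariates. A synthetic-cohort
    generator with planted ground-truth effects (voice waveforms, heart-rate
    streams, step counts and symptom diaries) makes every stage testable
    without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    lmerTest,
    signal,
    stats,
    utils,
    tools,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    optparse
Config/testthat/edition: 3
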