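Package: speechmarkers
Title: Connected-Speech Markers of Alzheimer's and Frontotemporal Dementia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated analysis of connected-speech transcripts for dementia
    phenotyping. Computes word-class ratios (nouns, verbs), grammatical-person
    ratios (first vs. third person markers, including pro-drop verb
    inflections), psycholinguistic word properties (log frequency,
    phonological neighborhood, phoneme length) and an embedding-based
    semantic-variability statistic from routine-description monologues.
    Provides group-level inference (2x2 mixed ANOVA with partial eta squared,
    Tukey HSD post hocs, one-tailed t-tests, Benjamini-Hochberg FDR, Dunnett
    many-to-one tests, chi-squared tables, feature-cognition correlations),
    subject-level classification (repeated stratified cross-validated linear
    SVM with coefficient-based feature importance and a hold-out
    generalizability protocol), and a seeded synthetic-cohort generator with
    planted, calibrated group effects for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    e1071,
    mvtnorm
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
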