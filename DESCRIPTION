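Package: refluxr
Title: Responder Analysis and Response Prediction for Daily Reflux Symptom Scores
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing symptomatic response to acid-suppressive
    therapy in gastro-oesophageal reflux disease from daily patient-reported
    symptom scores. Implements the consecutive-day responder rule on the
    ReQuest-GI sub-scale, a dual-threshold (grey-zone) prediction-level
    search over baseline and early-treatment scores, univariate and
    multivariate logistic screening of baseline factors, concordance of
    score-defined response with patient satisfaction and investigator
    assessment, and a calibrated synthetic cohort generator so the whole
    pipeline is testable without access to trial data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
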