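Package: eceq
Title: Scoring, Validation and Survey Planning for the Infantile Atopic
    Dermatitis Screening Questionnaire (eCEQ)
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the electronic modified Child Eczema Questionnaire
    (eCEQ), a seven-item caregiver-reported instrument that identifies
    infantile atopic dermatitis without a doctor's attendance. Provides
    rule-based and logistic-score classification of answer vectors,
    diagnostic-accuracy validation against a reference diagnosis
    (sensitivity, specificity, predictive values, Cohen's kappa, AUC),
    reconstruction of confusion matrices from published summary metrics,
    sample-size planning for diagnostic-accuracy and prevalence surveys,
    survey-export cleaning with staged exclusion accounting, awareness
    cascade reporting, and calibrated synthetic-cohort simulation for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    e1071,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
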