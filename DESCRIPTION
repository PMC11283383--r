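Package: cllclaims
Title: Treatment Patterns and Time-to-Event Analysis of Ibrutinib in
    Chronic Lymphocytic Leukaemia from Health-Insurance Claims
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for pharmacoepidemiological analysis of oral
    ibrutinib in chronic lymphocytic leukaemia (CLL) using national
    health-insurance claims extracts (patients, drug dispensations, hospital
    stays, long-term-disease statuses).  Provides a synthetic claims
    generator with planted ground truth, new-user cohort selection with an
    indication phenotyping algorithm (CLL/MCL/WM), treatment-regimen and
    line-of-treatment construction from pharmacy dispensations with a
    one-capsule-per-day gap rule, twelve-month comorbidity profiling with the
    Quan ICD-10 Charlson index and probabilistic cardiovascular markers,
    cardiovascular/bleeding safety-event detection, and estimation of time to
    next treatment (TTNT) and time to treatment discontinuation (TTD) by the
    Kaplan-Meier product-limit estimator and a Cox proportional-hazards model
    supporting a time-dependent hospitalization covariate.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
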