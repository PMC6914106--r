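Package: dtxcea
Title: Decision-Analytic Cost-Effectiveness Models for Digital Therapeutics in Type 2 Diabetes and Hypertension
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-arm decision-analytic cohort models estimating health resource
    use (HRU) savings and cost effectiveness of a digital therapeutic (DTx)
    added to treatment as usual (TAU) in type 2 diabetes and hypertension over
    a 3-year US-payer horizon. Clinical outcomes are tracked across four
    biomarker categories (HbA1c or systolic blood pressure); the models include
    program attrition with return-to-baseline rules, clinical-inertia delays
    before medication and cardiovascular-risk benefits accrue,
    category-gradient medication costs, cardiovascular event costs via hazard
    ratios or the Framingham general cardiovascular disease risk equation,
    QALY accrual from health-state utilities, deterministic one-way sensitivity
    analysis, break-even program-cost threshold curves, and an
    individual-level microsimulation oracle for validating the cohort engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
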