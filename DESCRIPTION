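Package: afscreen
Title: Single-Lead ECG Simulation and Atrial Fibrillation Screening Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates 15-second single-lead electrocardiograms with known
    rhythm, morphology and artifact ground truth, removes baseline wander with
    a linear-phase finite impulse response filter, extracts the rhythm features
    needed for atrial fibrillation detection (R peaks, RR-interval
    irregularity, P-wave presence, QRS amplitude), grades recording quality on
    a five-level artifact scale, applies a rule-based atrial fibrillation
    classifier (irregular RR intervals together with absent P waves), and
    evaluates screening performance as an age-stratified diagnostic-test table
    with exact binomial confidence intervals for sensitivity and specificity
    and standard logit intervals for the predictive values.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    stats,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
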