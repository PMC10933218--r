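Package: vatprofiler
Title: Visceral Adipose Tissue Distribution Profiling from Abdominal CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the craniocaudal distribution of visceral adipose
    tissue (VAT) in abdominal CT. Provides a synthetic CT phantom generator
    with ground-truth fat masks and vertebral landmarks, rule-based VAT/SAT
    segmentation by Hounsfield-unit windowing and compartment separation,
    vertebral-level slice planning, the standard body-composition indicators
    (visceral fat area, VAT volume, visceral adipose index, VAT ratio, and
    the lumbar mean/SD/coefficient of variation), and the discrimination
    statistics used to evaluate fat-distribution biomarkers: two- and
    three-group comparisons with corrected significance, logistic regression
    with odds ratios, ROC analysis with Youden cutoffs, and DeLong's test
    for correlated AUCs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    pROC,
    withr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
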