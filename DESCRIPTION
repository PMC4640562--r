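Package: clstest
Title: Clonal Likelihood Score Test for Tumor Pair Clonality
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies a pair of synchronous tumors as clonal
    (primary-metastatic) or independent from their somatic mutation
    profiles. Implements the Clonal Likelihood Score (CLS), the
    percentage of high-confidence somatic SNVs shared by both tumors,
    as a calibrated one-sided exact binomial test with Clopper-Pearson
    confidence intervals; stringent high-confidence mutation filtering
    from germline/tumor read evidence; exact power and sample-size
    design tables; counterfactual cross-patient cohort pairing to
    calibrate the background shared-mutation rate; and a Monte-Carlo
    simulator for verifying the test's operating characteristics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
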