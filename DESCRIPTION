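Package: screeneval
Title: Evaluation and Deployment Framework for AI Readers in Double-Read
    Breast Cancer Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating a standalone AI reader against human readers
    in double-read mammography screening programmes. Provides a synthetic
    screening-cohort generator with correlated reader decisions and
    device-conditional AI scores; ground-truth labelling under configurable
    follow-up windows; case-, breast- and lesion-level accuracy metrics
    including FROC analysis with intersection-over-union lesion matching;
    cluster-robust paired noninferiority and superiority inference
    (Obuchowski-type variance, clustered McNemar) with Holm-Bonferroni
    multiplicity control and case-level bootstrap; a double-reading workflow
    simulator with arbitration cost accounting; adaptive operating-point
    selection and drift monitoring; and subgroup fairness and calibration
    auditing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
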