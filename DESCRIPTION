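Package: sonomil
Title: Weakly Supervised Multiple-Instance Learning for Breast Ultrasound
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Breast-level malignancy prediction from variable-size breast
    ultrasound image sets using weakly supervised multiple-instance learning.
    Implements a convolutional backbone with per-image benign/malignant
    saliency maps, gated attention across the image set, top-t fraction
    saliency pooling and attention-weighted breast-level prediction, trained
    end-to-end from breast-level labels only. Ships a seeded synthetic
    ultrasound-phantom generator (speckle background, planted hypoechoic
    lesions with benign or spiculated malignant morphology), a training
    engine with random hyperparameter search and ensembling, test-time
    augmentation, a clinical cohort-eligibility rules engine with audit
    trail, and reader-study evaluation statistics (AUROC, AUPRC, matched
    operating points, hybrid reader-AI fusion, bootstrap confidence
    intervals, permutation tests, triage thresholds).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    jsonlite,
    png,
    optparse,
    yaml,
    stats,
    utils,
    tools
Suggests:
    pROC,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
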