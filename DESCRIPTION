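Package: taguchidetect
Title: Taguchi Orthogonal-Array Tuning Studies for Blood-Cell Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for running Taguchi orthogonal-array experiments that tune
    object-detection hyperparameters on blood-smear images. Provides the
    L9(3^4) design with orthogonality checking, signal-to-noise (SNR)
    summarization of replicate mean-average-precision (mAP) scores, response
    tables with best-level inference, and Taguchi ANOVA with percentage
    contributions. Detections are scored against ground truth with IoU
    matching, precision-recall curves, per-class average precision, mAP, and
    per-class counting accuracy. A synthetic smear-scene generator with a
    surrogate detector reproduces the statistical structure of the BCCD
    blood-cell dataset (RBC, WBC, platelet classes) so that full studies run
    in seconds on one CPU, and Pascal VOC XML annotation I/O connects the
    pipeline to real annotated images. Reference result tables from a
    GPU-trained ResNet50-SSD study are embedded so every derived quantity can
    be recomputed and checked from the raw replicate scores.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    xml2,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    png,
    optparse
Config/testthat/edition: 3
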