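Package: dermccm
Title: Perceptual Color Co-Occurrence Texture Features for Dermoscopic BCC Triage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Toolkit for basal cell carcinoma (BCC) triage from dermoscopic image
    tiles. Implements exact forward colorimetry (sRGB to XYZ, CIELAB and the
    CIECAM16 colour appearance model with its CAM16-UCS uniform space), perceptual
    colour-difference metrics, two-stage perceptual palette learning (per-pattern
    K-means followed by threshold-merged master palette) with nearest-centroid
    quantization, a Delta-E-weighted colour co-occurrence matrix (CCM) with five
    texture statistics alongside the classical GLCM, a trainable multilabel
    detector of seven BCC dermoscopic patterns, the clinical rule mapping pattern
    detections to a BCC/non-BCC diagnosis, evaluation metrics (sensitivity,
    specificity, PPV, ROC/AUC), and a seeded generator of pattern-labelled
    synthetic dermoscopic-like tiles for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    nnet,
    pROC
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    png
Config/testthat/edition: 3
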