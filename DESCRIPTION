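Package: acam
Title: Adaptive Contrast Adjustment for Grayscale Medical-Image Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a differentiable, content-adaptive contrast-generation
    block for grayscale medical-image classification. A shallow texture network
    predicts K image-specific contrast gains in the clinical range (1, 3); a
    mean-preserving linear contrast transform expands the input into a K-view
    stack that is fused into a downstream classifier. The package provides the
    contrast mathematics, the texture decision network with exact analytic
    gradients, a seeded six-class ultrasound speckle-phantom generator with
    recorded ideal restoring contrasts, training harnesses (plain, random
    contrast jittering, joint adaptive training, and a two-stage scheme that
    supervises the contrast generator before freezing it), and evaluation
    metrics (confusion matrices, precision/recall/F1, ROC/AUC, PR/AP).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    png
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
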