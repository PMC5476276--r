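Package: octquant
Title: Quantitative Retinal Layer Analysis for 3D Spectral-Domain OCT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies macular retinal layers on three-dimensional
    spectral-domain optical coherence tomography (SD-OCT) volumes using three
    indices: layer thickness, reference-normalized optical intensity ratio,
    and the optical-intensity attenuation coefficient (OIAC). Provides a
    layered Beer-Lambert speckle phantom generator with known ground truth,
    readers and writers for open volume and surface formats, a per-B-scan
    dynamic-programming surface segmenter with flattening and quality control,
    fovea-centered quadrant geometry, quality-adjusted reference-layer
    selection, attenuation-model calibration, and the accompanying statistical
    layer (normality-gated two-sample tests, correlation, chi-square, and ROC
    analysis with DeLong variance and paired AUC comparison).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    tiff,
    nortest
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
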