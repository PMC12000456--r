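Package: cystodl
Title: Ensemble Deep Learning for Endoscopic Bladder Tissue Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Diagnoses bladder tissue classes (high-grade carcinoma, low-grade
    carcinoma, non-suspicious tissue, no tumour lesion) from endoscopic images
    with an ensemble of three convolutional classifiers: a small CNN, a CNN
    trained on GAN-augmented data, and an explainable VGG-style branch whose
    Guided Grad-CAM saliency maps drive attention-guided crop augmentation.
    Includes interquartile-range outlier rejection for dataset curation, a
    two-scenario majority/accuracy-fallback voting rule, confusion-matrix
    metrics with macro and micro averaging, and a synthetic fixture generator
    with ground-truth lesion masks so the whole pipeline is testable without
    clinical data.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    png,
    jpeg,
    yaml,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
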