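Package: budquant
Title: Automated Tumor Budding Quantification in Pan-Cytokeratin IHC Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects and quantifies tumor buds in brightfield
    immunohistochemistry images of colorectal carcinoma stained for
    pan-cytokeratin (DAB) with hematoxylin counterstain. Provides color
    deconvolution in optical-density space, k-means foreground
    binarization, connected-component analysis with two-stage clustering
    and an area gate for bud candidates, a pluggable morphology
    classifier (small convolutional network or deterministic rules),
    virtual tissue-microarray gridding with per-tile bud statistics,
    Z-score hotspot detection, normalized Shannon entropy, Monte
    Carlo sampling-adequacy simulation, TMA dearraying with similarity
    registration, and detection-versus-ground-truth validation metrics.
    Ships a synthetic-image generator with exact ground truth so the
    whole pipeline is testable without slide data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    EBImage,
    deldir,
    sp,
    jsonlite,
    yaml,
    png,
    tiff
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
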