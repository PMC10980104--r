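Package: cardiogan
Title: GAN-Based Synthetic Data Augmentation for Cardiomyocyte Maturation Staging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how synthetic microscopy images produced by
    generative adversarial networks (GANs) improve the generalization of a
    convolutional classifier of cardiomyocyte maturation stage (day 2, 6, 14)
    under domain shift. Includes a procedural phantom simulator for
    microscopy-like cell fields and beating-cell clips, per-class image and
    video GANs with a compact CPU training loop, a small CNN maturation-stage
    classifier with random-crop augmentation, conventional machine-learning
    baselines, PCA distribution-fidelity analysis, confusion-matrix domain
    reports, and block-matching contractility quantification.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    png,
    jsonlite,
    yaml,
    e1071,
    randomForest,
    class,
    EBImage,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
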