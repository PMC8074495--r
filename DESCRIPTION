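Package: ppaRadiomics
Title: Optic-Disc-Region Radiomics for Myopic Maculopathy Grading
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Radiomics analysis of the optic disc region in color fundus
    photographs for severe myopic maculopathy. Implements ROI geometry
    (B-spline contour smoothing, mask rasterization, left-eye mirroring),
    a 322-column feature bank (clinic descriptors of disc tilt, torsion and
    peripapillary atrophy area; morphologic shape descriptors; first-order
    intensity statistics and GLCM/NGTDM texture features per color channel),
    a feature-mining cascade (z-score normalization, mutual-information and
    t-test filters, sequential floating forward selection scored by
    random-forest cross-validation), and an evaluation battery (ROC/AUC,
    univariate logistic cross-validated AUC, Pearson correlation, META-PM
    subclass profiles). A synthetic fundus phantom generator provides
    reproducible end-to-end test data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    png,
    tiff,
    jpeg,
    ranger,
    S4Vectors,
    SummarizedExperiment
Suggests:
    withr,
    testthat (>= 3.0.0),
    pROC,
    EBImage,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
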