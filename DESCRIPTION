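Package: amdgrade
Title: Texture-Based Screening and Grading of Age-Related Macular
    Degeneration from Fundus Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Automatic screening and grading of age-related macular
    degeneration (AMD) from colour fundus photographs in a telemedicine
    setting.  Implements the full pipeline: retina localisation and
    inscribed-square region-of-interest extraction with median-filter
    illumination normalisation; four feature families (multiresolution
    local binary patterns over a four-level Battle-Lemarie wavelet
    decomposition, RGB and L*a*b* colour histograms, histograms of
    oriented gradients, and a bag-of-visual-words over
    determinant-of-Hessian keypoints); Fisher-criterion and random-forest
    Gini-importance feature selection; one-vs-all Gaussian-kernel SVM and
    random-forest classifiers; and an evaluation protocol with stratified
    10-fold cross-validation, ROC/AUC with DeLong confidence intervals,
    confusion matrices, linearly weighted kappa, two-step grading, and a
    train-good/test-poor image-quality robustness split.  A seeded
    synthetic fundus-image generator with AREDS-category-dependent
    lesions and quality artifacts makes every stage testable without
    access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    e1071,
    grDevices,
    jsonlite,
    kernlab,
    png,
    ranger,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
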