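Package: mammodense
Title: Dense-Area Mammographic Image Features for Interval Versus
    Screen-Detected Breast Cancer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A case-case analysis pipeline that differentiates interval from
    screen-detected breast cancer using features of the dense area in
    pre-diagnostic mammograms. Provides a synthetic mammogram and cohort
    simulator with ground truth, image preprocessing (artifact removal,
    intensity normalization, pectoral-muscle removal), dense-area
    segmentation by Otsu, percentile and maximum-entropy (Kapur)
    thresholding, extraction of 32 dense-area image features (histogram,
    shape, texture, transform and filter-bank statistics), and the full
    statistical stage: Box-Cox standardization, percent-density-adjusted
    per-feature logistic tests, a global permutation test, forward AIC
    selection, multivariate odds-ratio models and stratified tumor-size
    regressions.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    EBImage,
    tiff,
    png,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    yaml,
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
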