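Package: adchist
Title: Full-Histogram ADC Classification of Parotid Gland Tumors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies parotid gland lesions (pleomorphic adenoma, Warthin
    tumor, malignant tumor) from whole-lesion apparent diffusion coefficient
    (ADC) voxel histograms. Per-patient histograms over fixed-width ADC bins
    are compared with pooled class-conditional reference distributions via a
    chi-squared discrepancy statistic, and the class with the smallest
    statistic is assigned. A mean-ADC comparator with Youden-index-optimal
    thresholds, pairwise sensitivity/specificity evaluation, leave-one-out,
    repeated stratified k-fold and out-of-bag bootstrap cross-validation, a
    reproducible synthetic cohort generator, and NIfTI map/mask voxel
    extraction are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    RNifti,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
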