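Package: pqctlong
Title: Longitudinal HR-pQCT Analysis of Bone Erosions and Enthesiophytes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for longitudinal analysis of cortical bone lesions
    (erosions and enthesiophytes) at the metacarpal heads imaged by
    high-resolution peripheral quantitative computed tomography (HR-pQCT).
    Provides a digital phantom generator with ground-truth lesions,
    baseline-indexed rigid co-registration by mutual-information
    maximization with trilinear re-slicing, slice matching and
    region-of-interest definition, seeded region-growing lesion volumetry,
    smallest-detectable-change (SDC) reliability estimation from repeated
    readings, SDC-thresholded progression classification, and the
    cohort-level group-comparison statistics (DAPSA disease-activity
    grouping, chi-square contingency tests, paired change tests) used to
    study five-year structural progression in psoriatic arthritis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
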