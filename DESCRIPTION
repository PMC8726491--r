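Package: femhu
Title: Opportunistic Osteoporosis Screening from Proximal-Femur CT Attenuation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for opportunistic osteoporosis screening on abdominal-pelvic
    CT using the proximal femur. Provides a seeded digital femur phantom cohort
    with ground-truth anatomy and bone-density-coupled tissue composition,
    Hounsfield-unit-bounded 3D region-growing segmentation of the proximal
    femur with lesser-trochanter cropping, femoral-neck axis estimation and
    true-coronal multiplanar reformation, HU-histogram analysis (fat and bone
    band percentages, mean HU) over 2D circular ROIs and 3D volumes of
    interest, and the diagnostic-statistics layer used to evaluate such
    indexes: Mann-Whitney AUC with DeLong confidence intervals and paired
    DeLong tests, Youden-index cutoffs with sensitivity/specificity/PPV/NPV,
    Spearman correlation with Fisher-z intervals, and two-way mixed-effects
    absolute-agreement intraclass correlation for interobserver reliability.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
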