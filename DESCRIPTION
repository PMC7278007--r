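Package: sctdose
Title: Dosimetric Evaluation of Segmentation-Based Synthetic CT for
    MRI-Only Brain Radiotherapy Planning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Desk-scale pipeline for assessing a six-tissue-class
    synthetic CT (sCT) conversion for MRI-only radiotherapy planning of
    the brain. Provides a seeded digital head-phantom cohort generator
    (co-registered CT/MR pairs with air, cortical bone, grey matter,
    white matter, CSF and soft tissue, a contrast-enhancing lesion and
    target structures), an EM tissue segmentation with HU lookup that
    assembles the sCT, bone segmentation metrics (Dice coefficient,
    bone volume, mean absolute HU error), a simplified divergent
    photon-beam dose engine for plan-copy recalculation on CT and sCT,
    ICRU-83 style dose-volume-histogram comparison with exact Wilcoxon
    signed-rank and Mann-Whitney U tests, and global 3D gamma-index
    analysis with a brute-force oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
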