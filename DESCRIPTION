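Package: rildseg
Title: Five-Class Radiation-Induced Lung Damage Segmentation on CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for voxel-wise classification of radiation-induced lung
    damage (RILD) on thoracic CT. Provides a synthetic CT phantom generator
    emulating the five-class tissue-density vocabulary (normal lung through
    consolidation) with realistic class imbalance, NIfTI input/output with
    strict grid-consistency checking, lung-masked preprocessing with
    pathology-driven slice filtering and patient-level cross-validation
    splits, three segmentation losses (frequency-weighted cross entropy,
    multiclass soft Dice, Lovasz-softmax) with analytic gradients, a compact
    2D U-Net implemented natively with logit-sum ensembling, and pooled
    (global) Dice evaluation with confusion matrices and
    annotation-refinement bookkeeping.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
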