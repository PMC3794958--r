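Package: subshape
Title: Subcortical Shape Analysis and Incremental PCA-LDA Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Surface-based shape analysis of subcortical structures
    (hippocampus and amygdala) for individual-subject classification of
    amyloid-positive ("mixed") versus amyloid-negative subcortical vascular
    dementia. Provides triangle-mesh differential operators and
    Laplace-Beltrami manifold harmonics, template-to-subject Laplacian
    surface deformation with vertex correspondence by construction,
    normal-direction deformity fields, spectral (manifold harmonic
    transform) feature extraction, PCA+LDA classification with exact
    incremental updating, cross-validated evaluation with ROC/AUC,
    permutation significance testing, learning curves, back-projected
    discriminative-region maps, PiB-PET SUVR-based amyloid labelling, and a
    synthetic cohort generator so the full pipeline is testable without
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    MASS,
    pROC
Config/testthat/edition: 3
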