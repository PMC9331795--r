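Package: artpredict
Title: Early Prediction of Adaptive Radiotherapy Need from CBCT Delta-Radiomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a delta-radiomics pipeline for the early prediction of
    significant volumetric changes (adaptive-replanning triage) in head and
    neck radiotherapy from weekly cone-beam CT (CBCT) regions of interest.
    Provides 3D gray-level texture matrices (GLCM, GLRLM, GLSZM, GLDM, NGTDM),
    a 104-feature-per-ROI radiomic bank (shape, first-order and second-order
    families), percentage-change delta-feature tables against the week-1
    baseline, linear-SVM recursive feature elimination with correlation bias
    reduction (RFE-CBR), leave-one-out cross-validated incremental subset
    search with permutation-based significance, and a synthetic longitudinal
    cohort generator (volume-level and feature-table-level) so that every
    stage of the analysis is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    igraph,
    jsonlite,
    pROC,
    RNifti
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
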