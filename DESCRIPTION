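Package: radphen
Title: DCE-MRI Radiomics Models of the CD8+ T-Cell Immunophenotype
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Radiomic modeling of the spatial CD8+ T-cell immunophenotype
    (immune-desert, immune-excluded, inflamed) of breast tumors from
    four-phase dynamic contrast-enhanced MRI. Provides volumetric image
    handling (subtraction images, isotropic resampling, peripheral-rim
    regions of interest, gray-level discretization), a 12-filter wavelet
    band-weighting bank, 833-feature radiomic feature groups built from
    first-order, GLCM, GLRLM, GLSZM and NGTDM texture families, ICC-based
    feature stability filtering, univariate-AUC feature ranking, LASSO
    score models with score- and feature-level multi-phase fusion, a
    two-stage three-class phenotype caller, the supporting statistical
    kernel (AUC, DeLong comparison, Holm adjustment, group comparisons,
    two-way random-effects ICC), and a synthetic DCE-MRI phantom cohort
    generator so the whole pipeline runs end to end without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    glmnet,
    RNifti,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
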