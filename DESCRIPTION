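Package: cicradiomics
Title: Radiogenomic Texture Analysis for CIC Mutation in Lower-Grade Glioma
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for radiogenomic analysis of CIC mutation
    status in lower-grade glioma: 3D radiomics texture features (first-order,
    GLCM, GLSZM, GLDM, NGTDM) computed from transformed MR volumes (wavelet
    sub-bands, pointwise intensity maps, gradient magnitude, local binary
    patterns), stability feature selection by repeated cross-validated Lasso,
    class-weighted logistic prediction evaluated over repeated stratified
    splits with averaged ROC/PR curves, plus mutation calling from variant
    tables, arm-level deletion calling from copy-number segments,
    chi-square/Mann-Whitney association tests and Kaplan-Meier/Cox survival
    analysis. A synthetic cohort generator (images, masks, genomic and
    clinical tables) makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    survival,
    igraph,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
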