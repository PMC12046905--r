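Package: HabitatRadiomics
Title: Habitat Radiomics Models of Occult Lymph Node Metastasis from CT Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for habitat radiomics analysis of head and neck squamous
    cell carcinoma CT: synthetic three-zone tumor phantom cohorts with
    clinical covariates and survival outcomes, peritumoral ring generation by
    physical dilation, voxel-level feature maps clustered into habitat
    subregions by K-means with Davies-Bouldin model selection, region-level
    radiomics feature extraction (shape, first-order, GLCM, GLRLM, GLSZM),
    a reproducibility/relevance/redundancy/LASSO feature-selection cascade,
    logistic regression, support vector machine and random forest classifiers
    of occult nodal status, ROC analysis with DeLong variance and model
    comparison, Youden cutoffs, calibration and decision curves, Kaplan-Meier
    and log-rank survival evaluation, and contingency-table baseline
    statistics with Wald odds ratios.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    RNifti,
    glmnet,
    randomForest,
    e1071,
    survival,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
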