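Package: pcrradiomics
Title: DCE-MRI Radiomics Models of Pathologic Complete Response to
    Neoadjuvant Chemotherapy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Predictive modelling of pathologic complete response (pCR)
    to neoadjuvant chemotherapy in breast cancer from DCE-MRI radiomics
    plus clinical, radiological and histological covariates. Implements
    the full analysis chain as reusable components: synthetic cohort and
    lesion-phantom generation; intensity normalization, isotropic
    cubic B-spline resampling and fixed-bin-count discretization; five
    radiomic features (mesh sphericity, Pearson kurtosis, GLDM dependence
    variance, GLRLM long-run high-gray-level emphasis, GLSZM
    high-gray-level zone emphasis); univariate Welch and Fisher exact
    screening; L1-penalized logistic feature reduction with leave-one-out
    cross-validated deviance; exhaustive covariate-subset model search
    over three classifiers with dual cross-validated AUC, Mason-Graham
    significance, false-discovery-rate correction, best-model feature
    frequencies and precision-weighted coefficient aggregation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    RNifti,
    e1071,
    randomForest,
    jsonlite,
    igraph,
    Matrix,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
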