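Package: bedrad
Title: Multiregional BED-Based Radiomics for Radiation Pneumonitis Risk after Lung SBRT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling the risk of symptomatic radiation pneumonitis
    after stereotactic body radiotherapy of the lung. Converts physical dose
    grids to biologically effective dose (BED) with the linear-quadratic model,
    builds dose-volume histogram metrics (Vx, V_BEDx, mean lung dose) and
    anatomical/dosimetric/BED-defined lung subregions, extracts shape,
    first-order and texture radiomic features, runs a four-stage feature
    selection cascade (Welch t-test, Pearson redundancy pruning, mRMR, LASSO
    with cross-validated lambda), trains and fuses per-region classifiers, and
    evaluates models with ROC/AUC, Hosmer-Lemeshow calibration and decision
    curve analysis. Includes a synthetic thoracic phantom cohort generator so
    the whole pipeline can be exercised and tested without patient data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    glmnet,
    pROC,
    e1071,
    ranger,
    xgboost,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
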