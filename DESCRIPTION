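Package: nirstack
Title: Stacked-Generalization Wavelength Selection and Calibration for Vis-NIR Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for multivariate calibration of visible/near-infrared
    (350-2500 nm) reflectance spectra of organic fertilizers. Implements a
    two-stage framework: wrapper wavelength selection by binary particle swarm
    optimization whose fitness is the cross-validated accuracy of a stacked
    generalization classifier over fertilizer varieties, followed by a stacked
    generalization regressor that predicts nitrogen and organic-matter
    concentrations from the selected channels. Includes Savitzky-Golay
    preprocessing, standardization, stratified calibration/prediction splits,
    baseline selectors (Lasso, genetic algorithm, PSO-SVM), Ridge/SVR/PLS
    reference regressors, R2/RMSE/limit-of-detection metrics, and a synthetic
    spectra generator reproducing the study design (9 varieties x 30 samples x
    3 replicate spectra on a 2151-channel grid) with known informative channels
    for selector-recovery benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    e1071,
    class,
    glmnet,
    nnet,
    randomForest,
    mixOmics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
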