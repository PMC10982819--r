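Package: milstage
Title: Weakly Supervised Lymph Node Metastasis Staging from Rectal MRI
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Trains node-level lymph-node metastasis classifiers for rectal
    cancer MRI using only patient-level pathology labels, by combining a
    multiple-instance learning head (max pooling of node probabilities
    against the binary metastasis label) with a learning-from-label-
    proportions head (mean node probability against the metastatic-node
    proportion among resected nodes). Provides a synthetic cohort simulator
    with matched population statistics, per-node morphometry (long/short
    axis diameters by minimum-area rotated rectangle, mean apparent
    diffusion coefficient), a small residual convolutional instance scorer
    with intensity/size/ADC fusion variants, gradient-weighted class
    activation heatmaps with intranodal/perinodal hotspot classification,
    and a full staging evaluation suite (ROC/AUC with DeLong comparison,
    count mean absolute error, ordinal concordance index, Cohen's kappa,
    F1, calibration and decision-curve analysis).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    EBImage,
    jsonlite,
    yaml,
    RNifti
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
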