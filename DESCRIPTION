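Package: trajvade
Title: Deep Embedding Clustering of Multi-Informant Psychopathology
    Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Clusters multivariate longitudinal psychometric trajectories
    with a recurrent variational deep embedding model: an LSTM
    autoencoder whose latent prior is a K-component Gaussian mixture,
    trained jointly with learned imputation values so that incomplete
    trajectories are handled inside the model. Includes a synthetic
    cohort generator with known trajectory classes and known
    covariate-to-class log-odds for validation, iterative random-forest
    item imputation, pooled z-standardization, prediction-strength
    selection of the number of clusters, and baseline-predictor analysis
    via chained-equation multiple imputation, multinomial logistic
    regression and Rubin's rules.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    nnet,
    ranger,
    jsonlite,
    yaml
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
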