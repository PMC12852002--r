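Package: pcgstack
Title: Heart-Sound Texture and Deep-Feature Stacking Ensembles for HFpEF Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A phonocardiogram (PCG) analysis pipeline for detecting heart
    failure with preserved ejection fraction (HFpEF) from single-channel
    heart-sound recordings. Implements signal conditioning (Butterworth
    bandpass, FIR mains notch, SVD plus wavelet denoising, resampling,
    z-scoring), gammatone-filterbank spectrograms, gray-level texture
    matrices (GLCM, GLRLM, GLSZM, GLDM) with the standard 70-feature
    radiomics panel, a pluggable deep-feature backbone with PCA reduction,
    four calibrated base learners (RFE-SVM on texture, PCA random forests
    on deep features), an AUC-weighted stacking ensemble with a multilayer
    perceptron meta-learner, subject-grouped evaluation with the DeLong
    test, Gaussian-process Bayesian hyperparameter optimization, and a
    seeded synthetic heart-sound simulator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    signal,
    e1071,
    randomForest,
    igraph,
    lhs,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
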