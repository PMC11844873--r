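Package: parksev
Title: Predicting Parkinson's Disease Severity from Resting-State fMRI Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting Movement Disorder Society Unified Parkinson's
    Disease Rating Scale (MDS-UPDRS) total scores from resting-state fMRI
    features combined with clinical and demographic variables. Implements
    voxelwise regional homogeneity (Kendall's coefficient of concordance),
    ALFF and fractional ALFF maps, one-step nuisance confound regression,
    framewise-displacement quality control, atlas merging and label
    resampling, regional feature extraction, longitudinal visit matching,
    nested cross-validation (leave-one-out outer loop, k-fold inner loop)
    over four model families, permutation-based chance levels, post-hoc
    severity classification, and median feature importance. Ships a
    synthetic-data generator producing 4D volumes with known local temporal
    coherence and in-band spectral power, motion traces, and cohorts that
    follow a known linear generative model, so the entire pipeline can be
    exercised end-to-end with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    RNifti,
    glmnet,
    e1071,
    randomForest,
    xgboost,
    signal,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    vegan,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
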