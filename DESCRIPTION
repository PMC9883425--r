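Package: pathRS
Title: Deep-Feature Pathological Risk Scores for Survival Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds and validates a whole-slide-image (WSI) pathological
    risk score for time-to-event prognosis. Tumor regions of interest are
    tiled into fixed-size patches and stain-normalized by optical-density
    (Macenko-style) decomposition; patches are featurized by a pluggable
    2048-dimensional backbone; an autoencoder compresses patch features to
    a 128-dimensional deep-encode representation; patient-level vectors
    are obtained by per-dimension averaging; salient dimensions are found
    by repeated-subsample elasticnet-Cox stability selection; a Cox
    signature is normalized by the cohort root-mean-square into a risk
    score and dichotomized at a log-rank-maximizing cutpoint. Includes a
    synthetic cohort generator with planted prognostic signal and a full
    survival-evaluation suite (Harrell's C, IPCW time-dependent AUC,
    Kaplan-Meier/log-rank, Cox hazard-ratio tables, clinicopathological
    subgroup stratification, contingency-table tests).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    survival,
    glmnet,
    jsonlite,
    yaml,
    png
Suggests:
    testthat (>= 3.0.0),
    withr,
    tiff
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'utils.R'
    'synthetic-cohort.R'
    'slide-prep.R'
    'deep-features.R'
    'autoencoder.R'
    'patient-features.R'
    'stability-selection.R'
    'risk-model.R'
    'survival-eval.R'
    'pipeline.R'
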