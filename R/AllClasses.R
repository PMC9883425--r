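#' Per-patient matrix of backbone patch features
#'
#' Container for the high-dimensional (2048-d) features of all patches
#' sampled from one patient's slide. Rows follow the patch manifest order
#' (row-major tiling), so feature matrices are reproducible.
#'
#' @slot patientId character scalar.
#' @slot features numeric matrix, `n_patches x 2048`, nonnegative, finite.
#' @slot backboneId character scalar naming the feature source.
#'
#' @examples
#' pfs <- PatchFeatureSet("p1", matrix(abs(rnorm(2 * 2048)), 2), "surrogate")
#' dim(featureMatrix(pfs))
#' @export
setClass("PatchFeatureSet",
         representation(patientId = "character",
                        features = "matrix",
                        backboneId = "character"))

setValidity("PatchFeatureSet", function(object) {
  msg <- character()
  if (length(object@patientId) != 1L || is.na(object@patientId))
    msg <- c(msg, "patientId must be a single non-NA string")
  if (ncol(object@features) != 2048L)
    msg <- c(msg, "feature matrix must have exactly 2048 columns")
  if (nrow(object@features) < 1L)
    msg <- c(msg, "feature matrix must have at least one patch row")
  if (!all(is.finite(object@features)))
    msg <- c(msg, "feature matrix contains NaN/Inf")
  if (length(msg)) msg else TRUE
})

#' Constructor for [PatchFeatureSet-class]
#' @param patientId character scalar.
#' @param features `n_patches x 2048` numeric matrix.
#' @param backboneId character scalar.
#' @return A validated `PatchFeatureSet`.
#' @export
PatchFeatureSet <- function(patientId, features, backboneId = "unknown") {
  new("PatchFeatureSet", patientId = as.character(patientId),
      features = as.matrix(features), backboneId = backboneId)
}

#' @describeIn PatchFeatureSet-class patient identifier
#' @param object a `PatchFeatureSet`.
#' @export
setMethod("patientId", "PatchFeatureSet", function(object) object@patientId)

#' @describeIn PatchFeatureSet-class the patch-by-feature matrix
#' @export
setMethod("featureMatrix", "PatchFeatureSet", function(object) object@features)

#' @describeIn PatchFeatureSet-class name of the feature source
#' @export
setMethod("backboneId", "PatchFeatureSet", function(object) object@backboneId)

setMethod("show", "PatchFeatureSet", function(object) {
  cat("PatchFeatureSet for patient", object@patientId, "\n")
  cat(" ", nrow(object@features), "patches x", ncol(object@features),
      "features; backbone:", object@backboneId, "\n")
})

#' Per-patient matrix of deep-encode (DE) features
#'
#' The 128-dimensional autoencoder-bottleneck representation of each
#' patch's backbone features.
#'
#' @slot patientId character scalar.
#' @slot codes numeric matrix, `n_patches x 128`, finite.
#' @export
setClass("DEFeatureSet",
         representation(patientId = "character", codes = "matrix"))

setValidity("DEFeatureSet", function(object) {
  msg <- character()
  if (ncol(object@codes) != 128L)
    msg <- c(msg, "code matrix must have exactly 128 columns")
  if (!all(is.finite(object@codes)))
    msg <- c(msg, "code matrix contains NaN/Inf")
  if (length(msg)) msg else TRUE
})

#' Constructor for [DEFeatureSet-class]
#' @param patientId character scalar.
#' @param codes `n_patches x 128` numeric matrix.
#' @return A validated `DEFeatureSet`.
#' @export
DEFeatureSet <- function(patientId, codes) {
  new("DEFeatureSet", patientId = as.character(patientId),
      codes = as.matrix(codes))
}

#' @describeIn DEFeatureSet-class patient identifier
#' @param object a `DEFeatureSet`.
#' @export
setMethod("patientId", "DEFeatureSet", function(object) object@patientId)

#' @describeIn DEFeatureSet-class the patch-by-code matrix
#' @export
setMethod("featureMatrix", "DEFeatureSet", function(object) object@codes)

setMethod("show", "DEFeatureSet", function(object) {
  cat("DEFeatureSet for patient", object@patientId, ":",
      nrow(object@codes), "patches x", ncol(object@codes), "codes\n")
})

#' Trained autoencoder (encoder + decoder + input scaler)
#'
#' Dense 2048-512-128-512-2048 autoencoder with rectified-linear hidden
#' layers, trained by minibatch Adam on mean squared reconstruction error.
#' The min-max input scaler fitted on the training pool is stored with the
#' weights so that encoding is fully deterministic given the object.
#'
#' @slot weights list of weight matrices `W1..W4` and bias vectors `b1..b4`.
#' @slot scaler list with per-dimension `min` and `range` of the training pool.
#' @slot spec list echoing the training specification (see [autoencoderSpec()]).
#' @slot history data.frame with one row per epoch: train/validation MSE and
#'   the reconstruction-accuracy surrogate (fraction of entries within 0.05).
#' @export
setClass("AutoencoderModel",
         representation(weights = "list", scaler = "list",
                        spec = "list", history = "data.frame"))

setMethod("show", "AutoencoderModel", function(object) {
  w <- object@weights
  cat("AutoencoderModel:",
      paste(c(nrow(w$W1), sapply(w[paste0("W", 1:4)], ncol)), collapse = "-"),
      "\n")
  if (nrow(object@history)) {
    last <- object@history[nrow(object@history), ]
    cat(sprintf("  trained %d epochs; final MSE train %.4g / validation %.4g\n",
                nrow(object@history), last$train_mse, last$val_mse))
  } else cat("  untrained (initial weights)\n")
})

#' Result of repeated-subsample elasticnet-Cox stability selection
#'
#' @slot frequency integer vector: per-feature count of subsample repeats in
#'   which the feature's elasticnet-Cox coefficient was nonzero.
#' @slot selectedIdx integer vector of selected (1-based) feature indices,
#'   ordered by decreasing frequency, ties broken by lower index.
#' @slot nRepeats number of subsample repeats.
#' @slot subsampleFraction fraction of training patients per repeat.
#' @slot seed integer seed that reproduces the subsample sequence.
#' @slot params list of elastic-net settings (alpha, nfolds, ...).
#' @export
setClass("SelectionResult",
         representation(frequency = "integer", selectedIdx = "integer",
                        nRepeats = "integer", subsampleFraction = "numeric",
                        seed = "integer", params = "list"))

setValidity("SelectionResult", function(object) {
  msg <- character()
  if (any(object@frequency < 0L) || any(object@frequency > object@nRepeats))
    msg <- c(msg, "frequencies must lie in [0, nRepeats]")
  if (anyDuplicated(object@selectedIdx))
    msg <- c(msg, "selected indices must be unique")
  if (length(msg)) msg else TRUE
})

#' @describeIn SelectionResult-class selected feature indices
#' @param object a `SelectionResult`.
#' @export
setMethod("selectedIdx", "SelectionResult", function(object) object@selectedIdx)

#' @describeIn SelectionResult-class per-feature selection frequencies
#' @export
setMethod("selectionFrequency", "SelectionResult",
          function(object) object@frequency)

setMethod("show", "SelectionResult", function(object) {
  cat("SelectionResult:", length(object@selectedIdx), "features selected of",
      length(object@frequency), "after", object@nRepeats, "repeats\n")
  cat("  top indices:", paste(utils::head(object@selectedIdx, 8L),
                              collapse = ", "), "...\n")
})

#' Fitted risk-score model
#'
#' Cox proportional-hazards signature on the selected patient-level DE
#' features, plus the cohort root-mean-square normalization constant and
#' the risk-score cutpoint, both frozen from the training cohort.
#'
#' @slot endpoint `"OS"` or `"DFS"`.
#' @slot selectedIdx integer indices of the signature features.
#' @slot beta named numeric vector of Cox log-hazard coefficients.
#' @slot rmsNorm `sqrt(mean(signature^2))` over the training cohort; the
#'   divisor that converts a signature into a risk score.
#' @slot cutpoint risk-score threshold; `score >= cutpoint` is high risk.
#' @slot tiesMethod partial-likelihood tie handling (`"efron"`/`"breslow"`).
#' @slot cutpointScan data.frame audit trail of the cutpoint search
#'   (candidate, log-rank chi-square, group sizes).
#' @export
setClass("RiskModel",
         representation(endpoint = "character", selectedIdx = "integer",
                        beta = "numeric", rmsNorm = "numeric",
                        cutpoint = "numeric", tiesMethod = "character",
                        cutpointScan = "data.frame"))

setValidity("RiskModel", function(object) {
  msg <- character()
  if (length(object@beta) != length(object@selectedIdx))
    msg <- c(msg, "one coefficient per selected feature required")
  if (length(object@rmsNorm) == 1L && !is.na(object@rmsNorm) &&
      object@rmsNorm <= 0)
    msg <- c(msg, "rmsNorm must be positive")
  if (length(msg)) msg else TRUE
})

#' @describeIn RiskModel-class indices of the signature features
#' @param object a `RiskModel`.
#' @export
setMethod("selectedIdx", "RiskModel", function(object) object@selectedIdx)

setMethod("show", "RiskModel", function(object) {
  cat("RiskModel [", object@endpoint, "]: ", length(object@beta),
      " features, rmsNorm = ", signif(object@rmsNorm, 4),
      ", cutpoint = ", signif(object@cutpoint, 4), "\n", sep = "")
})
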