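# Block-mean downsample of a matrix to pool x pool.
blockMean <- function(m, pool) {
  ry <- floor((seq_len(nrow(m)) - 1L) * pool / nrow(m))
  rx <- floor((seq_len(ncol(m)) - 1L) * pool / ncol(m))
  s <- rowsum(m, ry)
  s <- t(rowsum(t(s), rx))
  cnt <- outer(tabulate(ry + 1L, pool), tabulate(rx + 1L, pool))
  s / cnt
}

#' Deterministic surrogate feature backbone
#'
#' A drop-in stand-in for a pretrained convolutional backbone: each patch
#' is block-mean downsampled to `pool x pool` per channel, and the
#' resulting pixel-statistics vector is passed through a fixed random
#' linear projection to 2048 dimensions followed by a rectifier. The
#' projection is fully determined by `seed`, so features are reproducible
#' across machines with no weight files.
#'
#' @param seed integer seed fixing the projection.
#' @param pool downsampling grid side (default 16).
#' @return A list of class `"BackboneSpec"` with `id`, `type = "surrogate"`,
#'   `pool`, `seed` and the projection matrix.
#' @export
surrogateBackbone <- function(seed = 1L, pool = 16L) {
  d <- 3L * pool^2
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  W <- matrix(rnorm(2048L * d, sd = 1 / sqrt(d)), 2048L, d)
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  structure(list(id = sprintf("surrogate-pool%d-seed%d", pool, seed),
                 type = "surrogate", pool = as.integer(pool),
                 seed = as.integer(seed), W = W),
            class = "BackboneSpec")
}

#' Pretrained-CNN backbone placeholder
#'
#' Declares the convolutional path (global-average-pool head of a
#' 2048-wide pretrained network, inputs resized to 224 and channel
#' standardized). Extraction through this path requires external weights;
#' without them [extractFeatures()] raises an explicit error directing the
#' caller to the surrogate backbone.
#'
#' @param weightPath optional path to serialized weights.
#' @return A `"BackboneSpec"` list.
#' @export
cnnBackbone <- function(weightPath = NULL) {
  structure(list(id = "cnn-gap-2048", type = "cnn", weightPath = weightPath,
                 inputSize = 224L), class = "BackboneSpec")
}

#' Extract 2048-dimensional features for a list of patches
#'
#' One feature row per patch, in the order of the patch list (which should
#' follow the row-major patch manifest). Extraction is deterministic for a
#' fixed backbone and inputs, and commutes with partitioning the patch
#' list.
#'
#' @param patches list of `H x W x 3` RGB arrays in \[0,1\].
#' @param backbone a `"BackboneSpec"`, e.g. [surrogateBackbone()].
#' @param patientId identifier recorded on the result.
#' @return A [PatchFeatureSet-class].
#' @export
extractFeatures <- function(patches, backbone = surrogateBackbone(),
                            patientId = "patient") {
  stopIfNot(inherits(backbone, "BackboneSpec"), "backbone must be a BackboneSpec")
  stopIfNot(length(patches) >= 1L, "at least one patch is required")
  if (backbone$type == "cnn") {
    if (is.null(backbone$weightPath) || !file.exists(backbone$weightPath))
      stop("pretrained CNN weights not available; supply weightPath or use ",
           "surrogateBackbone()", call. = FALSE)
    stop("CNN inference is not bundled; use surrogateBackbone()",
         call. = FALSE)
  }
  feats <- t(vapply(patches, function(p) {
    v <- unlist(lapply(1:3, function(ch) blockMean(p[, , ch], backbone$pool)))
    pmax(drop(backbone$W %*% v), 0)
  }, numeric(2048L)))
  PatchFeatureSet(patientId, feats, backbone$id)
}
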