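#' Autoencoder training specification
#'
#' Fixed 2048-512-128-512-2048 dense architecture with rectified-linear
#' hidden layers (including the 128-wide bottleneck) and a linear output,
#' trained by minibatch Adam on mean squared reconstruction error. Inputs
#' are min-max scaled to \[0,1\] per dimension by default, with the scaler
#' fitted on the training pool and stored with the model.
#'
#' @param batchSize minibatch size (default 32).
#' @param epochs training epochs (default 150).
#' @param learningRate Adam step size (default 1e-3).
#' @param trainFractionPerPatient fraction of each patient's patches pooled
#'   into the autoencoder dataset (default 0.10; see [buildAEDataset()]).
#' @param valFraction fraction of the pooled rows held out for validation.
#' @param accuracyTol absolute tolerance defining the reconstruction
#'   "accuracy" surrogate: the fraction of reconstructed entries within
#'   this distance of the scaled input. Reported per epoch, never used for
#'   model selection.
#' @param scaleInputs logical; min-max scale inputs per dimension.
#' @param seed integer seed for initialization and shuffling.
#' @return A list of class `"AutoencoderSpec"`.
#' @export
autoencoderSpec <- function(batchSize = 32L, epochs = 150L,
                            learningRate = 1e-3,
                            trainFractionPerPatient = 0.10,
                            valFraction = 0.2, accuracyTol = 0.05,
                            scaleInputs = TRUE, seed = 1L) {
  stopIfNot(trainFractionPerPatient > 0 && trainFractionPerPatient <= 1,
            "trainFractionPerPatient must be in (0, 1]")
  structure(list(widths = c(2048L, 512L, 128L, 512L, 2048L),
                 batchSize = as.integer(batchSize),
                 epochs = as.integer(epochs), learningRate = learningRate,
                 trainFractionPerPatient = trainFractionPerPatient,
                 valFraction = valFraction, accuracyTol = accuracyTol,
                 scaleInputs = isTRUE(scaleInputs), seed = as.integer(seed)),
            class = "AutoencoderSpec")
}

#' Build the autoencoder train/validation pool
#'
#' Samples `ceil(fraction * n_patches)` feature rows per patient without
#' replacement (so every patient contributes at least one row), pools them,
#' and splits the pool into training and validation parts.
#'
#' @param featureSets list of [PatchFeatureSet-class].
#' @param fraction per-patient sampling fraction (default 0.10).
#' @param valFraction validation share of the pool (default 0.2).
#' @param seed integer seed; fixed seed reproduces the split exactly.
#' @return A list with matrices `train` and `validation`.
#' @export
buildAEDataset <- function(featureSets, fraction = 0.10, valFraction = 0.2,
                           seed = 1L) {
  stopIfNot(length(featureSets) >= 1L, "empty feature set list")
  set.seed(seed)
  rows <- lapply(featureSets, function(fs) {
    m <- featureMatrix(fs)
    stopIfNot(nrow(m) >= 1L, "every patient needs at least one patch")
    k <- ceiling(fraction * nrow(m))
    m[sample.int(nrow(m), k), , drop = FALSE]
  })
  pool <- do.call(rbind, rows)
  ord <- sample.int(nrow(pool))
  pool <- pool[ord, , drop = FALSE]
  nVal <- floor(valFraction * nrow(pool))
  if (nVal == 0L || nVal == nrow(pool)) {
    list(train = pool, validation = pool)
  } else {
    list(train = pool[seq_len(nrow(pool) - nVal), , drop = FALSE],
         validation = pool[(nrow(pool) - nVal + 1L):nrow(pool), , drop = FALSE])
  }
}

relu <- function(x) x * (x > 0)

# Glorot-uniform weight init with zero biases. The smaller Glorot scale
# (vs He) keeps the rectified bottleneck from collapsing early on the
# all-nonnegative inputs this model sees.
aeInitWeights <- function(widths) {
  w <- list()
  for (l in 1:4) {
    lim <- sqrt(6 / (widths[l] + widths[l + 1]))
    w[[paste0("W", l)]] <- matrix(runif(widths[l] * widths[l + 1],
                                        -lim, lim),
                                  widths[l], widths[l + 1])
    w[[paste0("b", l)]] <- rep(0, widths[l + 1])
  }
  w
}

aeForward <- function(X, w) {
  H1 <- relu(sweep(X %*% w$W1, 2, w$b1, `+`))
  Z <- relu(sweep(H1 %*% w$W2, 2, w$b2, `+`))
  H3 <- relu(sweep(Z %*% w$W3, 2, w$b3, `+`))
  Y <- sweep(H3 %*% w$W4, 2, w$b4, `+`)
  list(H1 = H1, Z = Z, H3 = H3, Y = Y)
}

aeScale <- function(X, scaler) {
  sweep(sweep(X, 2, scaler$min, `-`), 2, scaler$range, `/`)
}

#' Train the autoencoder
#'
#' @param train training matrix (rows x 2048), raw feature scale.
#' @param validation validation matrix; `NULL` reuses `train`.
#' @param spec an [autoencoderSpec()].
#' @return An [AutoencoderModel-class] with per-epoch history.
#' @export
trainAutoencoder <- function(train, validation = NULL,
                             spec = autoencoderSpec()) {
  validation <- validation %||% train
  stopIfNot(ncol(train) == 2048L, "training matrix must have 2048 columns")
  set.seed(spec$seed)
  scaler <- if (spec$scaleInputs) {
    mn <- apply(train, 2, min)
    rg <- apply(train, 2, max) - mn
    list(min = mn, range = ifelse(rg > 0, rg, 1))
  } else list(min = rep(0, 2048L), range = rep(1, 2048L))
  Xtr <- aeScale(train, scaler)
  Xva <- aeScale(validation, scaler)

  w <- aeInitWeights(spec$widths)
  m <- lapply(w, function(p) p * 0)
  v <- lapply(w, function(p) p * 0)
  b1a <- 0.9; b2a <- 0.999; eps <- 1e-8; t <- 0L
  hist <- vector("list", spec$epochs)
  n <- nrow(Xtr)

  for (ep in seq_len(spec$epochs)) {
    ord <- sample.int(n)
    starts <- seq(1L, n, by = spec$batchSize)
    epLoss <- 0
    for (s in starts) {
      idx <- ord[s:min(s + spec$batchSize - 1L, n)]
      X <- Xtr[idx, , drop = FALSE]
      f <- aeForward(X, w)
      nb <- nrow(X)
      err <- f$Y - X
      loss <- mean(err^2)
      if (!is.finite(loss))
        stop("autoencoder training diverged (non-finite loss) at epoch ", ep,
             call. = FALSE)
      epLoss <- epLoss + loss * nb
      dY <- 2 * err / length(err)
      g <- list()
      g$W4 <- crossprod(f$H3, dY); g$b4 <- colSums(dY)
      dH3 <- tcrossprod(dY, w$W4) * (f$H3 > 0)
      g$W3 <- crossprod(f$Z, dH3); g$b3 <- colSums(dH3)
      dZ <- tcrossprod(dH3, w$W3) * (f$Z > 0)
      g$W2 <- crossprod(f$H1, dZ); g$b2 <- colSums(dZ)
      dH1 <- tcrossprod(dZ, w$W2) * (f$H1 > 0)
      g$W1 <- crossprod(X, dH1); g$b1 <- colSums(dH1)
      t <- t + 1L
      for (nm in names(w)) {
        m[[nm]] <- b1a * m[[nm]] + (1 - b1a) * g[[nm]]
        v[[nm]] <- b2a * v[[nm]] + (1 - b2a) * g[[nm]]^2
        mh <- m[[nm]] / (1 - b1a^t)
        vh <- v[[nm]] / (1 - b2a^t)
        w[[nm]] <- w[[nm]] - spec$learningRate * mh / (sqrt(vh) + eps)
      }
    }
    fv <- aeForward(Xva, w)
    valErr <- fv$Y - Xva
    hist[[ep]] <- data.frame(
      epoch = ep, train_mse = epLoss / n, val_mse = mean(valErr^2),
      val_accuracy = mean(abs(valErr) <= spec$accuracyTol))
  }
  history <- if (spec$epochs) do.call(rbind, hist) else
    data.frame(epoch = integer(), train_mse = numeric(),
               val_mse = numeric(), val_accuracy = numeric())
  new("AutoencoderModel", weights = w, scaler = scaler,
      spec = unclass(spec), history = history)
}

#' Encode backbone features into 128-dimensional DE features
#'
#' Applies the stored input scaler and the encoder half of the trained
#' autoencoder; row `i` of the output is the bottleneck activation for row
#' `i` of the input. Deterministic given a trained model.
#'
#' @param features a [PatchFeatureSet-class] or a numeric matrix with 2048
#'   columns.
#' @param model an [AutoencoderModel-class].
#' @return A [DEFeatureSet-class] (for a `PatchFeatureSet` input) or a
#'   matrix with 128 columns.
#' @export
encodeFeatures <- function(features, model) {
  stopIfNot(is(model, "AutoencoderModel"), "model must be an AutoencoderModel")
  X <- if (is(features, "PatchFeatureSet")) featureMatrix(features)
       else as.matrix(features)
  stopIfNot(ncol(X) == nrow(model@weights$W1),
            "feature width does not match the encoder input width")
  Xs <- aeScale(X, model@scaler)
  w <- model@weights
  H1 <- relu(sweep(Xs %*% w$W1, 2, w$b1, `+`))
  Z <- relu(sweep(H1 %*% w$W2, 2, w$b2, `+`))
  if (is(features, "PatchFeatureSet")) DEFeatureSet(patientId(features), Z)
  else Z
}

#' Serialize / restore an autoencoder as JSON
#'
#' Model checkpoints are written as plain JSON (weights, scaler, spec,
#' history) so runs are portable and diffable.
#'
#' @param model an [AutoencoderModel-class].
#' @param path output path.
#' @return `writeAutoencoder`: invisibly, `path`. `readAutoencoder`: the
#'   restored model.
#' @export
writeAutoencoder <- function(model, path) {
  jsonlite::write_json(
    list(weights = lapply(model@weights, unclass),
         scaler = model@scaler, spec = model@spec, history = model@history),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeAutoencoder
#' @export
readAutoencoder <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  w <- x$weights
  for (l in 1:4) {
    w[[paste0("W", l)]] <- as.matrix(w[[paste0("W", l)]])
    w[[paste0("b", l)]] <- as.numeric(w[[paste0("b", l)]])
  }
  new("AutoencoderModel", weights = w,
      scaler = list(min = as.numeric(x$scaler$min),
                    range = as.numeric(x$scaler$range)),
      spec = x$spec, history = as.data.frame(x$history))
}
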