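#' Ground truth for a synthetic whole-slide-image cohort
#'
#' Bundles every parameter of the synthetic data-generating process so that
#' downstream stages can be validated against a known truth. Patch features
#' arise from a small number of latent factors through a nonnegative loading
#' matrix (so they resemble post-activation CNN outputs); survival times
#' follow a Weibull proportional-hazards model whose linear predictor uses
#' only the prognostic latent factors; censoring is an independent uniform
#' follow-up window.
#'
#' The Weibull baseline scale is, by default, calibrated at simulation time
#' so that the realized overall-survival censored fraction matches
#' `censorRate`; the relapse-process scale is likewise calibrated so the
#' disease-free-survival event fraction matches `dfsEventRate`. Defaults
#' (`censorRate = 0.9`, `dfsEventRate = 0.19`, follow-up 60-100 months)
#' emulate a cervical-cancer cohort with roughly 10% deaths and 19%
#' recurrences over a 5-8 year follow-up.
#'
#' @param nLatent number of latent factors (default 10).
#' @param prognosticIdx 1-based indices of hazard-driving factors.
#' @param betaTrue length-`nLatent` log-hazard coefficients; entries outside
#'   `prognosticIdx` are ignored (treated as zero).
#' @param baselineShape Weibull shape of the baseline hazard.
#' @param baselineScale Weibull scale in months, or `NULL` to calibrate
#'   against `censorRate` at simulation time.
#' @param censorRate target fraction of censored overall-survival records.
#' @param dfsEventRate target fraction of disease-free-survival events, or
#'   `NULL` for `min(0.95, 1.9 * (1 - censorRate))` (the death:recurrence
#'   proportion of the emulated cohort).
#' @param followUp length-2 numeric, uniform follow-up window in months.
#' @param loadingMatrix `2048 x nLatent` nonnegative loadings, or `NULL` to
#'   draw once per simulation seed.
#' @param noiseSd per-feature additive noise standard deviation.
#' @param jitterSd per-patch latent jitter standard deviation.
#' @return A list of class `"GroundTruth"`.
#' @seealso [simulateCohort()]
#' @export
groundTruth <- function(nLatent = 10L, prognosticIdx = 1:3,
                        betaTrue = c(1, 1, -1, rep(0, 7)),
                        baselineShape = 1.5, baselineScale = NULL,
                        censorRate = 0.9, dfsEventRate = NULL,
                        followUp = c(60, 100), loadingMatrix = NULL,
                        noiseSd = 0.1, jitterSd = 0.3) {
  stopIfNot(nLatent >= 1, "nLatent must be >= 1")
  stopIfNot(all(prognosticIdx >= 1 & prognosticIdx <= nLatent),
            "prognosticIdx must index the latent factors")
  stopIfNot(length(betaTrue) == nLatent,
            "betaTrue must have one coefficient per latent factor")
  stopIfNot(censorRate >= 0 && censorRate < 1, "censorRate must be in [0,1)")
  stopIfNot(noiseSd >= 0, "noiseSd must be nonnegative")
  if (!is.null(loadingMatrix))
    stopIfNot(nrow(loadingMatrix) == 2048L && ncol(loadingMatrix) == nLatent,
              "loadingMatrix must be 2048 x nLatent")
  structure(list(nLatent = as.integer(nLatent),
                 prognosticIdx = as.integer(prognosticIdx),
                 betaTrue = betaTrue, baselineShape = baselineShape,
                 baselineScale = baselineScale, censorRate = censorRate,
                 dfsEventRate = dfsEventRate, followUp = followUp,
                 loadingMatrix = loadingMatrix, noiseSd = noiseSd,
                 jitterSd = jitterSd),
            class = "GroundTruth")
}

# Calibrate a Weibull scale so that the expected censored fraction over the
# drawn linear predictors and censor times equals `target`.
# S(t | lp) = exp(-(t/scale)^shape * exp(lp)).
calibrateScale <- function(lp, ctimes, shape, target,
                           extraLogSurv = NULL) {
  survAt <- function(logScale) {
    s <- exp(-(ctimes / exp(logScale))^shape * exp(lp))
    if (!is.null(extraLogSurv)) s <- s * exp(extraLogSurv)
    mean(s)
  }
  f <- function(ls) survAt(ls) - target
  lo <- log(1e-3); hi <- log(1e6)
  if (f(hi) < 0) return(exp(hi))   # even a huge scale gives too many events
  if (f(lo) > 0) return(exp(lo))
  exp(stats::uniroot(f, c(lo, hi), tol = 1e-8)$root)
}

# Draw OS/DFS outcomes from Weibull PH with uniform-window censoring.
# Returns a data.frame plus the calibrated scales. Consumes the active RNG
# stream; callers set the seed.
simulateSurvival <- function(lp, truth) {
  n <- length(lp)
  ctimes <- runif(n, truth$followUp[1], truth$followUp[2])
  scaleOS <- truth$baselineScale %||%
    calibrateScale(lp, ctimes, truth$baselineShape, truth$censorRate)
  tDeath <- scaleOS * (-log(runif(n)) / exp(lp))^(1 / truth$baselineShape)
  osTime <- pmin(tDeath, ctimes)
  osEvent <- as.integer(tDeath <= ctimes)

  dfsTarget <- truth$dfsEventRate %||%
    min(0.95, 1.9 * (1 - truth$censorRate))
  # relapse hazard shares the linear predictor; its scale is calibrated so
  # that P(death or relapse before censoring) matches the DFS event target
  logSurvDeath <- -(ctimes / scaleOS)^truth$baselineShape * exp(lp)
  feasible <- mean(exp(logSurvDeath))        # max achievable DFS censor frac
  dfsCensorTarget <- min(1 - dfsTarget, feasible)
  scaleDFS <- calibrateScale(lp, ctimes, truth$baselineShape,
                             dfsCensorTarget, extraLogSurv = logSurvDeath)
  tRelapse <- scaleDFS * (-log(runif(n)) / exp(lp))^(1 / truth$baselineShape)
  tProg <- pmin(tDeath, tRelapse)
  dfsTime <- pmin(tProg, ctimes)
  dfsEvent <- as.integer(tProg <= ctimes)

  list(outcome = data.frame(os_time = osTime, os_event = osEvent,
                            dfs_time = dfsTime, dfs_event = dfsEvent),
       scaleOS = scaleOS, scaleDFS = scaleDFS)
}

# Clinical covariates drawn independently of survival (pure noise), with
# category frequencies typical of an early-stage cervical-cancer cohort.
simulateClinical <- function(n) {
  lnMet <- rbinom(n, 1, 0.20)
  data.frame(
    age = round(runif(n, 29, 75), 1),
    figo_stage = sample(c("IB1", "IB2", "IIA1", "IIA2"), n, TRUE,
                        prob = c(0.61, 0.12, 0.22, 0.05)),
    histology = sample(c("squamous", "adenocarcinoma", "adenosquamous"),
                       n, TRUE, prob = c(0.94, 0.05, 0.01)),
    margin_positive = rbinom(n, 1, 0.015),
    parametrial_invasion = rbinom(n, 1, 0.015),
    ln_metastasis = lnMet,
    ln_positive_count = ifelse(lnMet == 1, 1 + stats::rpois(n, 1.2), 0),
    lvsi = rbinom(n, 1, 0.17),
    dsi_deep = rbinom(n, 1, 0.58),            # stromal invasion > 1/2
    tumor_size_cm = round(runif(n, 0.5, 6.5), 1),
    stringsAsFactors = FALSE)
}

#' Simulate a cohort of patch-feature sets with planted prognostic signal
#'
#' Per patient, a latent factor vector is drawn; each patch observes the
#' latent vector plus patch-level jitter through the nonnegative loading
#' matrix, plus feature noise, clipped at zero. Overall and disease-free
#' survival are generated from a Weibull proportional-hazards model on the
#' prognostic latent factors with independent uniform-window censoring, so
#' `dfs_time <= os_time` by construction. Clinical covariates are drawn
#' independently of survival (they carry no signal and serve as the noise
#' baseline for model comparison).
#'
#' @param nPatients number of patients (>= 2).
#' @param patchesPerPatient length-2 integer range of patches per patient.
#' @param truth a [groundTruth()] object.
#' @param seed integer seed; fixed seed gives byte-identical output.
#' @return A list with elements `records` (data.frame, one row per patient:
#'   identifiers, outcomes, clinical covariates), `features` (list of
#'   [PatchFeatureSet-class]), `latent` (patient-by-factor score matrix),
#'   and `truth` (the input truth with calibrated Weibull scales filled in).
#' @examples
#' cohort <- simulateCohort(20, c(3, 5), seed = 1)
#' head(cohort$records[, 1:5])
#' @export
simulateCohort <- function(nPatients, patchesPerPatient = c(8L, 16L),
                           truth = groundTruth(), seed = 1L) {
  stopIfNot(nPatients >= 2, "nPatients must be >= 2")
  stopIfNot(all(patchesPerPatient >= 1), "patch counts must be positive")
  set.seed(seed)
  p <- truth$nLatent
  Z <- matrix(rnorm(nPatients * p), nPatients, p)
  beta <- rep(0, p)
  beta[truth$prognosticIdx] <- truth$betaTrue[truth$prognosticIdx]
  lp <- drop(Z %*% beta)

  surv <- simulateSurvival(lp, truth)
  truth$baselineScale <- surv$scaleOS
  truth$relapseScale <- surv$scaleDFS

  clin <- simulateClinical(nPatients)
  records <- cbind(data.frame(patient_id = sprintf("P%03d", seq_len(nPatients)),
                              stringsAsFactors = FALSE),
                   surv$outcome, clin)

  L <- truth$loadingMatrix %||%
    matrix(abs(rnorm(2048 * p)) / sqrt(p), 2048L, p)
  truth$loadingMatrix <- L
  counts <- sample(seq(patchesPerPatient[1], patchesPerPatient[2]),
                   nPatients, replace = TRUE)
  features <- lapply(seq_len(nPatients), function(i) {
    E <- matrix(Z[i, ], counts[i], p, byrow = TRUE) +
      matrix(rnorm(counts[i] * p, sd = truth$jitterSd), counts[i], p)
    X <- E %*% t(L) + matrix(rnorm(counts[i] * 2048L, sd = truth$noiseSd),
                             counts[i], 2048L)
    PatchFeatureSet(records$patient_id[i], pmax(X, 0), "synthetic-latent")
  })
  checkCohort(records)
  list(records = records, features = features, latent = Z, truth = truth)
}

#' Simulate a cohort with planted signal directly in deep-encode dimensions
#'
#' Generates patient-level 128-dimensional feature vectors where a few
#' dimensions carry a planted log-hazard and the rest are noise — the
#' natural ground truth for validating stability selection and signature
#' fitting without running the feature-extraction stages.
#'
#' @param nPatients number of patients.
#' @param nFeatures number of feature dimensions (default 128).
#' @param prognosticIdx indices of hazard-carrying dimensions.
#' @param beta log-hazard coefficients, one per `prognosticIdx` entry.
#' @param censorRate target censored fraction of the simulated endpoint.
#' @param followUp uniform follow-up window in months.
#' @param seed integer seed.
#' @return A list with `pde` (patient-by-feature matrix), `records`
#'   (outcomes + clinical noise covariates), and `lp` (true linear
#'   predictor).
#' @export
simulateDECohort <- function(nPatients, nFeatures = 128L,
                             prognosticIdx = 1:3, beta = c(1, 1, -1),
                             censorRate = 0.81, followUp = c(60, 100),
                             seed = 1L) {
  stopIfNot(nPatients >= 2, "nPatients must be >= 2")
  stopIfNot(length(beta) == length(prognosticIdx),
            "one coefficient per prognostic index required")
  set.seed(seed)
  M <- matrix(rnorm(nPatients * nFeatures), nPatients, nFeatures,
              dimnames = list(NULL, sprintf("de_%03d", seq_len(nFeatures) - 1L)))
  lp <- drop(M[, prognosticIdx, drop = FALSE] %*% beta)
  tr <- groundTruth(censorRate = censorRate, followUp = followUp)
  surv <- simulateSurvival(lp, tr)
  records <- cbind(data.frame(patient_id = sprintf("P%03d", seq_len(nPatients)),
                              stringsAsFactors = FALSE),
                   surv$outcome, simulateClinical(nPatients))
  list(pde = M, records = records, lp = lp)
}

#' Simulate toy stained-tissue slides with ROI masks
#'
#' Produces small RGB images containing a textured two-stain "tissue"
#' region on a bright background, under an optional per-patient linear
#' color shift (emulating scanner/staining variation), plus binary ROI
#' masks marking the tissue. The images exist to exercise tiling and stain
#' normalization; they make no attempt at realistic histomorphology.
#'
#' @param nPatients number of slides.
#' @param imageSize square image side in pixels; must be `>= patchSize`.
#' @param stainShift `"random"` for per-patient channel gains in
#'   \[0.75, 1.25\], `"identity"` for none, or a list of length-3 gain
#'   vectors (one per patient).
#' @param patchSize the patch size the slides must accommodate.
#' @param seed integer seed.
#' @return A list with `images` (list of `imageSize x imageSize x 3` arrays
#'   in \[0,1\]), `masks` (list of 0/1 matrices), and `ids`.
#' @export
simulateToySlides <- function(nPatients, imageSize = 256L,
                              stainShift = "random", patchSize = 64L,
                              seed = 1L) {
  stopIfNot(imageSize >= patchSize,
            "imageSize must be at least one patch in each dimension")
  set.seed(seed)
  # reference H&E stain vectors in optical density (unit norm)
  H <- c(0.65, 0.70, 0.29); H <- H / sqrt(sum(H^2))
  E <- c(0.07, 0.99, 0.11); E <- E / sqrt(sum(E^2))
  n <- imageSize
  xy <- expand.grid(y = seq_len(n), x = seq_len(n))
  cx <- (xy$x - n / 2) / n; cy <- (xy$y - n / 2) / n
  inBlob <- (cx^2 / 0.16 + cy^2 / 0.12) <= 1

  gains <- switch(
    if (is.character(stainShift)) stainShift else "list",
    identity = replicate(nPatients, c(1, 1, 1), simplify = FALSE),
    random = replicate(nPatients, runif(3, 0.75, 1.25), simplify = FALSE),
    list = stainShift)

  images <- vector("list", nPatients)
  masks <- vector("list", nPatients)
  for (i in seq_len(nPatients)) {
    f1 <- runif(3, 2, 9); f2 <- runif(3, 2, 9); ph <- runif(4, 0, 2 * pi)
    c1 <- 0.55 + 0.35 * sin(f1[1] * pi * cx + ph[1]) *
      cos(f1[2] * pi * cy + ph[2]) + rnorm(n * n, sd = 0.08)
    c2 <- 0.35 + 0.25 * sin(f2[1] * pi * cx + ph[3]) *
      cos(f2[2] * pi * cy + ph[4]) + rnorm(n * n, sd = 0.08)
    c1 <- pmax(c1, 0) * inBlob
    c2 <- pmax(c2, 0) * inBlob
    od <- cbind(c1, c2) %*% rbind(H, E)         # n*n x 3 optical densities
    img <- 10^(-od)                             # transmitted light in (0,1]
    img <- sweep(img, 2, gains[[i]], `*`)
    img[!inBlob, ] <- pmin(img[!inBlob, , drop = FALSE] * 0 + 0.97, 1)
    arr <- array(pmin(pmax(img, 0), 1), dim = c(n, n, 3))
    images[[i]] <- arr
    masks[[i]] <- matrix(as.integer(inBlob), n, n)
  }
  list(images = images, masks = masks,
       ids = sprintf("P%03d", seq_len(nPatients)))
}

#' Write a simulated cohort to disk
#'
#' Writes the per-patient metadata table as CSV and one patch-feature CSV
#' per patient (patch rows, 2048 named feature columns).
#'
#' @param cohort result of [simulateCohort()].
#' @param dir output directory (created if absent).
#' @return Invisibly, the metadata CSV path.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- file.path(dir, "cohort.csv")
  write.csv(cohort$records, meta, row.names = FALSE)
  fdir <- file.path(dir, "features")
  dir.create(fdir, showWarnings = FALSE)
  for (fs in cohort$features) {
    m <- featureMatrix(fs)
    colnames(m) <- sprintf("f_%04d", seq_len(ncol(m)) - 1L)
    write.csv(as.data.frame(m),
              file.path(fdir, paste0(patientId(fs), ".csv")),
              row.names = FALSE)
  }
  invisible(meta)
}

#' Write toy slides and masks as PNG
#'
#' @param slides result of [simulateToySlides()].
#' @param dir output directory.
#' @return Invisibly, the directory.
#' @export
writeToySlides <- function(slides, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(slides$ids)) {
    png::writePNG(slides$images[[i]],
                  file.path(dir, paste0(slides$ids[i], ".png")))
    png::writePNG(slides$masks[[i]] + 0.0,
                  file.path(dir, paste0(slides$ids[i], "_mask.png")))
  }
  invisible(dir)
}
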