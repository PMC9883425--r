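#' Stability selection by repeated-subsample elasticnet-Cox fits
#'
#' Repeatedly draws a 50% patient subsample (without replacement) from the
#' training cohort, fits an elastic-net-penalized Cox model on the
#' subsample with the penalty chosen by cross-validated partial likelihood,
#' and records which features have nonzero coefficients at that penalty.
#' Features are ranked by their selection frequency across repeats and the
#' top 15% are returned as the salient PDE features. Subsamples with fewer
#' than 2 events (or failed penalized fits) are redrawn, up to 100 attempts
#' per repeat.
#'
#' Patients are processed in sorted-identifier order, so the frequency
#' vector is invariant to the row order of the inputs for a fixed seed.
#'
#' @param pde patient-by-feature matrix, rownames = patient ids.
#' @param records cohort outcome table (one row per patient).
#' @param endpoint `"OS"` or `"DFS"`.
#' @param nRepeats number of subsample repeats (default 1000; 50-1500 are
#'   the supported working range).
#' @param subsampleFraction fraction of patients per subsample (default 0.5).
#' @param enetParams list: `alpha` elastic-net mixing (default 0.5),
#'   `nfolds` for the cross-validated penalty (default 5), and the penalty
#'   path controls `nlambda` (default 50) and `lambdaMinRatio` (default
#'   0.05).
#' @param topFraction fraction of features to keep (default 0.15).
#' @param exactCount override the selected-feature count with an exact
#'   number (e.g. 18), ignoring `topFraction`.
#' @param seed integer seed.
#' @return A [SelectionResult-class].
#' @export
stabilitySelect <- function(pde, records, endpoint = "OS",
                            nRepeats = 1000L, subsampleFraction = 0.5,
                            enetParams = list(alpha = 0.5, nfolds = 5L),
                            topFraction = 0.15, exactCount = NULL,
                            seed = 1L) {
  stopIfNot(nRepeats >= 1L, "nRepeats must be a positive count")
  stopIfNot(subsampleFraction > 0 && subsampleFraction < 1,
            "subsampleFraction must be in (0, 1)")
  ord <- order(rownames(pde))
  pde <- pde[ord, , drop = FALSE]
  records <- records[match(rownames(pde), records$patient_id), ]
  cols <- endpointCols(endpoint)
  time <- records[[cols["time"]]]
  event <- records[[cols["event"]]]
  stopIfNot(sum(event) > 0, paste("endpoint", endpoint, "has zero events"))

  p <- ncol(pde)
  keep <- apply(pde, 2, function(x) stats::sd(x) > 0)
  if (!all(keep))
    warning(sum(!keep), " constant feature column(s) dropped", call. = FALSE)
  X <- pde[, keep, drop = FALSE]

  alpha <- enetParams$alpha %||% 0.5
  nfolds <- enetParams$nfolds %||% 5L
  nlambda <- enetParams$nlambda %||% 50L
  lambdaMinRatio <- enetParams$lambdaMinRatio %||% 0.05
  n <- nrow(X)
  m <- max(2L, floor(subsampleFraction * n))
  freq <- rep(0L, p)

  set.seed(seed)
  for (r in seq_len(nRepeats)) {
    nz <- NULL
    for (attempt in seq_len(100L)) {
      idx <- sample.int(n, m)
      if (sum(event[idx]) < 2L) next
      fit <- tryCatch(
        suppressWarnings(glmnet::cv.glmnet(
          X[idx, , drop = FALSE],
          survival::Surv(time[idx], event[idx]),
          family = "cox", alpha = alpha, nfolds = nfolds,
          nlambda = nlambda, lambda.min.ratio = lambdaMinRatio)),
        error = function(e) NULL)
      if (!is.null(fit)) {
        cf <- as.numeric(stats::coef(fit, s = "lambda.min"))
        nz <- which(cf != 0)
        break
      }
    }
    if (is.null(nz))
      stop("could not draw a usable subsample (too few events?)",
           call. = FALSE)
    if (length(nz)) {
      full <- which(keep)[nz]
      freq[full] <- freq[full] + 1L
    }
  }

  k <- as.integer(exactCount %||% round(topFraction * p))
  eligible <- which(keep)
  ranked <- eligible[order(-freq[eligible], eligible)]
  if (k > length(ranked)) {
    warning("fewer non-degenerate features than requested; selecting ",
            length(ranked), call. = FALSE)
    k <- length(ranked)
  }
  selected <- ranked[seq_len(k)]
  new("SelectionResult", frequency = freq, selectedIdx = as.integer(selected),
      nRepeats = as.integer(nRepeats), subsampleFraction = subsampleFraction,
      seed = as.integer(seed),
      params = list(alpha = alpha, nfolds = nfolds, endpoint = endpoint,
                    topFraction = topFraction, exactCount = exactCount,
                    droppedConstant = which(!keep)))
}

#' Compare stability-selection repeat counts by downstream discrimination
#'
#' For each repeat count, runs selection on the training cohort, fits the
#' Cox signature on the selected features, scores the testing cohort, and
#' reports the test-cohort Harrell's C — the screening-times comparison
#' used to justify the number of random screenings.
#'
#' @param pde patient-by-feature matrix (full cohort).
#' @param records outcome table (full cohort).
#' @param split a [splitCohort()] result.
#' @param endpoint `"OS"` or `"DFS"`.
#' @param repeatGrid integer vector of repeat counts, e.g.
#'   `c(50, 100, 500, 1000, 1500)`.
#' @param seed integer seed (shared across grid entries).
#' @param ... further arguments to [stabilitySelect()].
#' @return A data.frame with columns `n_repeats`, `n_selected`,
#'   `c_index_test`.
#' @export
compareRepeatCounts <- function(pde, records, split, endpoint = "OS",
                                repeatGrid = c(50L, 100L, 500L, 1000L, 1500L),
                                seed = 1L, ...) {
  trIdx <- rownames(pde) %in% split$trainIds
  teIdx <- rownames(pde) %in% split$testIds
  cols <- endpointCols(endpoint)
  recTr <- records[match(rownames(pde)[trIdx], records$patient_id), ]
  recTe <- records[match(rownames(pde)[teIdx], records$patient_id), ]
  rows <- lapply(repeatGrid, function(nr) {
    sel <- stabilitySelect(pde[trIdx, , drop = FALSE], recTr,
                           endpoint = endpoint, nRepeats = nr,
                           seed = seed, ...)
    sig <- fitSignature(pde[trIdx, , drop = FALSE], recTr,
                        selectedIdx(sel), endpoint = endpoint)
    lpTest <- drop(pde[teIdx, selectedIdx(sel), drop = FALSE] %*% sig$beta)
    cidx <- harrellC(recTe[[cols["time"]]], recTe[[cols["event"]]], lpTest)
    data.frame(n_repeats = nr, n_selected = length(selectedIdx(sel)),
               c_index_test = cidx$c)
  })
  do.call(rbind, rows)
}
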