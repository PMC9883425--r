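#' Fit the multivariable Cox signature on selected PDE features
#'
#' Maximizes the Cox partial likelihood (Efron tie handling by default)
#' over the selected feature columns and computes the training-cohort
#' root-mean-square of the resulting signatures,
#' `rmsNorm = sqrt(sum(Sig_k^2) / n)` — the constant that later converts a
#' signature into a risk score. The normalization is frozen on the
#' training cohort and reused unchanged on test data.
#'
#' @param pde patient-by-feature matrix.
#' @param records outcome table aligned by `patient_id`.
#' @param selIdx integer indices of the signature features.
#' @param endpoint `"OS"` or `"DFS"`.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @param onSeparation `"error"` (default) to fail on monotone likelihood,
#'   naming the offending features; `"drop"` to remove them and refit
#'   (with a warning), as one would when an event-poor cohort cannot
#'   support the full signature.
#' @return A list: `beta` (named coefficients), `rmsNorm`, `signatures`
#'   (training linear predictors), `selIdx` (features actually kept),
#'   `fit` (the underlying proportional-hazards fit).
#' @export
fitSignature <- function(pde, records, selIdx, endpoint = "OS",
                         ties = c("efron", "breslow"),
                         onSeparation = c("error", "drop")) {
  ties <- match.arg(ties)
  onSeparation <- match.arg(onSeparation)
  records <- records[match(rownames(pde), records$patient_id), ]
  cols <- endpointCols(endpoint)
  time <- records[[cols["time"]]]
  event <- records[[cols["event"]]]
  stopIfNot(sum(event) >= 2L, "at least 2 events required to fit a signature")
  selIdx <- as.integer(selIdx)
  for (round in 1:6) {
    X <- pde[, selIdx, drop = FALSE]
    sds <- apply(X, 2, stats::sd)
    stopIfNot(all(sds > 0),
              paste("selected features are constant:",
                    paste(selIdx[sds == 0], collapse = ", ")))
    fit <- survival::coxph(survival::Surv(time, event) ~ X, ties = ties)
    beta <- stats::coef(fit)
    # scale-invariant divergence check: effect per SD of the feature
    bad <- !is.finite(beta) | abs(beta * sds) > 50
    if (!any(bad)) break
    if (onSeparation == "error" || round == 6 || all(bad))
      stop("signature fit did not converge (monotone likelihood?) for ",
           "feature(s): ", paste(selIdx[bad], collapse = ", "),
           call. = FALSE)
    warning("dropping separating feature(s) ",
            paste(selIdx[bad], collapse = ", "), " and refitting",
            call. = FALSE)
    selIdx <- selIdx[!bad]
  }
  names(beta) <- colnames(X) %||% paste0("f", selIdx)
  sig <- drop(X %*% beta)
  list(beta = beta, rmsNorm = sqrt(mean(sig^2)), signatures = sig,
       selIdx = selIdx, fit = fit)
}

#' Normalize signatures by the cohort root-mean-square
#'
#' `score_i = sig_i / sqrt(sum_k(sig_k^2) / n)`. By construction the mean
#' of the squared scores is exactly 1 (`sum(score^2) = n`).
#'
#' @param signatures numeric vector of Cox linear predictors.
#' @param rmsNorm optionally, a pre-computed (training-cohort) divisor; by
#'   default the root-mean-square of `signatures` itself.
#' @return Numeric vector of risk scores.
#' @examples
#' rmsNormalize(c(3, 4))  # 0.8485, 1.1314
#' @export
rmsNormalize <- function(signatures, rmsNorm = NULL) {
  if (is.null(rmsNorm)) rmsNorm <- sqrt(mean(signatures^2))
  stopIfNot(is.finite(rmsNorm) && rmsNorm > 0,
            "signatures are all zero; risk scores undefined")
  signatures / rmsNorm
}

#' Find the risk-score cutpoint by log-rank maximization
#'
#' Emulates X-tile-style optimal-cutpoint search: scans the midpoints of
#' consecutive unique scores, keeping only candidates that leave at least
#' `minGroupFraction` of patients and at least one event on each side, and
#' returns the candidate maximizing the two-group log-rank chi-square. The
#' full scan table is returned for audit. No multiplicity correction is
#' applied to the scan (a single threshold is chosen and reused).
#'
#' @param scores training-cohort risk scores.
#' @param records training outcome table (rows aligned with `scores`).
#' @param endpoint `"OS"` or `"DFS"`.
#' @param minGroupFraction minimum group share per side (default 0.10).
#' @return A list: `cutpoint`, `chisq`, and `scan` (data.frame: cutpoint,
#'   chisq, n_low, n_high).
#' @export
findCutpoint <- function(scores, records, endpoint = "OS",
                         minGroupFraction = 0.10) {
  cols <- endpointCols(endpoint)
  time <- records[[cols["time"]]]
  event <- records[[cols["event"]]]
  stopIfNot(length(scores) == nrow(records),
            "scores and records must align")
  stopIfNot(sum(event) >= 2L, "at least 2 events required")
  u <- sort(unique(scores))
  stopIfNot(length(u) >= 2L, "all scores are equal; no cutpoint exists")
  cands <- (u[-1] + u[-length(u)]) / 2
  n <- length(scores)
  minN <- max(1L, ceiling(minGroupFraction * n))
  rows <- lapply(cands, function(ct) {
    hi <- scores >= ct
    nHi <- sum(hi); nLo <- n - nHi
    if (nHi < minN || nLo < minN) return(NULL)
    if (sum(event[hi]) < 1L || sum(event[!hi]) < 1L) return(NULL)
    sd <- survival::survdiff(survival::Surv(time, event) ~ hi)
    data.frame(cutpoint = ct, chisq = sd$chisq, n_low = nLo, n_high = nHi)
  })
  scan <- do.call(rbind, rows)
  stopIfNot(!is.null(scan) && nrow(scan) > 0,
            "no cutpoint satisfies the group-size/event constraints")
  best <- which.max(scan$chisq)
  list(cutpoint = scan$cutpoint[best], chisq = scan$chisq[best], scan = scan)
}

#' Fit a complete risk model (signature + normalization + cutpoint)
#'
#' Convenience constructor tying [fitSignature()], [rmsNormalize()] and
#' [findCutpoint()] together on the training cohort.
#'
#' @inheritParams fitSignature
#' @inheritParams findCutpoint
#' @return A [RiskModel-class].
#' @export
fitRiskModel <- function(pde, records, selIdx, endpoint = "OS",
                         ties = "efron", minGroupFraction = 0.10,
                         onSeparation = "error") {
  sig <- fitSignature(pde, records, selIdx, endpoint = endpoint,
                      ties = ties, onSeparation = onSeparation)
  scores <- rmsNormalize(sig$signatures, sig$rmsNorm)
  records <- records[match(rownames(pde), records$patient_id), ]
  cp <- findCutpoint(scores, records, endpoint = endpoint,
                     minGroupFraction = minGroupFraction)
  new("RiskModel", endpoint = toupper(endpoint),
      selectedIdx = as.integer(sig$selIdx), beta = sig$beta,
      rmsNorm = sig$rmsNorm, cutpoint = cp$cutpoint,
      tiesMethod = ties, cutpointScan = cp$scan)
}

#' Apply a fitted risk model to a cohort
#'
#' Scores use the training-cohort `rmsNorm` and cutpoint unchanged, so the
#' same threshold stratifies training and testing cohorts. High risk is
#' `score >= cutpoint`.
#'
#' @param model a [RiskModel-class].
#' @param pde patient-by-feature matrix (any cohort).
#' @return A data.frame: `patient_id`, `signature`, `score`, `group`
#'   (`"high"`/`"low"`).
#' @export
applyRiskModel <- function(model, pde) {
  stopIfNot(max(model@selectedIdx) <= ncol(pde),
            "pde matrix lacks the model's selected features")
  sig <- drop(pde[, model@selectedIdx, drop = FALSE] %*% model@beta)
  score <- rmsNormalize(sig, model@rmsNorm)
  data.frame(patient_id = rownames(pde) %||% seq_len(nrow(pde)),
             signature = sig, score = score,
             group = ifelse(score >= model@cutpoint, "high", "low"),
             stringsAsFactors = FALSE)
}

#' Serialize a risk model as JSON
#'
#' @param model a [RiskModel-class].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writeRiskModel <- function(model, path) {
  jsonlite::write_json(
    list(endpoint = model@endpoint, selectedIdx = model@selectedIdx,
         beta = as.list(model@beta), rmsNorm = model@rmsNorm,
         cutpoint = model@cutpoint, tiesMethod = model@tiesMethod),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
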