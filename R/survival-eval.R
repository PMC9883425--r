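#' @importFrom survival Surv coxph survfit survdiff concordance
NULL

# Percentile bootstrap over patients for a scalar statistic.
bootCI <- function(stat, n, nBoot, seed, confLevel = 0.95) {
  set.seed(seed)
  reps <- vapply(seq_len(nBoot), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    tryCatch(stat(idx), error = function(e) NA_real_)
  }, numeric(1))
  a <- (1 - confLevel) / 2
  stats::quantile(reps, c(a, 1 - a), na.rm = TRUE, names = FALSE)
}

#' Harrell's concordance index for censored survival data
#'
#' `C = (concordant + 0.5 * tied-score) / comparable`, where a pair is
#' comparable iff the earlier observed time is an event; higher scores are
#' expected to fail earlier. The optional confidence interval is a seeded
#' nonparametric percentile bootstrap over patients.
#'
#' @param times observed times.
#' @param events 0/1 event indicators.
#' @param scores risk scores (higher = higher risk).
#' @param nBoot bootstrap draws for the CI (0 = no CI; default 0,
#'   1000 is the reporting default).
#' @param seed bootstrap seed.
#' @param confLevel CI level.
#' @return A list: `c`, `comparable` (pair count), and `ci` when requested.
#' @examples
#' harrellC(c(3, 5, 8), c(1, 1, 1), c(3, 2, 1))$c  # 1
#' @export
harrellC <- function(times, events, scores, nBoot = 0L, seed = 1L,
                     confLevel = 0.95) {
  stopIfNot(length(times) == length(events) && length(times) == length(scores),
            "times, events, scores must have equal length")
  stopIfNot(sum(events) >= 1, "at least one event required")
  cfit <- survival::concordance(survival::Surv(times, events) ~ scores,
                                reverse = TRUE)
  cnt <- cfit$count
  comparable <- sum(cnt[c("concordant", "discordant", "tied.x")])
  stopIfNot(comparable > 0, "no comparable pairs")
  out <- list(c = unname(cfit$concordance), comparable = unname(comparable))
  if (nBoot > 0L) {
    out$ci <- bootCI(function(idx) {
      f <- survival::concordance(
        survival::Surv(times[idx], events[idx]) ~ scores[idx], reverse = TRUE)
      unname(f$concordance)
    }, length(times), nBoot, seed, confLevel)
  }
  out
}

#' Log-rank test across groups
#'
#' Standard observed-minus-expected log-rank statistic with hypergeometric
#' variance; p-value from the chi-square distribution on `groups - 1`
#' degrees of freedom.
#'
#' @param times observed times.
#' @param events 0/1 event indicators.
#' @param groups group labels (>= 2 distinct values).
#' @return A list: `chisq`, `df`, `p`.
#' @export
logrankTest <- function(times, events, groups) {
  groups <- as.factor(groups)
  stopIfNot(nlevels(droplevels(groups)) >= 2L,
            "log-rank test needs at least two groups")
  sd <- survival::survdiff(survival::Surv(times, events) ~ groups)
  df <- length(sd$n) - 1L
  list(chisq = unname(sd$chisq), df = df,
       p = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Kaplan-Meier product-limit estimate
#'
#' @param times observed times.
#' @param events 0/1 event indicators.
#' @return A list: `table` (time, n_risk, n_event, n_censor, surv) and
#'   `surv`, a right-continuous step function with `surv(0) = 1` that
#'   drops only at event times.
#' @export
kmEstimate <- function(times, events) {
  stopIfNot(length(times) >= 1L, "empty input")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  tab <- data.frame(time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, n_censor = fit$n.censor,
                    surv = fit$surv)
  sf <- if (nrow(tab)) stats::stepfun(tab$time, c(1, tab$surv))
        else function(t) rep(1, length(t))
  list(table = tab, surv = sf)
}

# Left-continuous censoring-survival function G(t-) from the KM estimate
# of the censoring distribution.
censoringSurvMinus <- function(times, events) {
  fit <- survival::survfit(survival::Surv(times, 1 - events) ~ 1)
  if (!length(fit$time)) return(function(t) rep(1, length(t)))
  stats::stepfun(fit$time, c(1, fit$surv), right = TRUE)
}

#' IPCW time-dependent (cumulative/dynamic) AUC at a horizon
#'
#' Cases are subjects with an observed event by the horizon; controls are
#' subjects still event-free past the horizon. Cases are weighted by the
#' inverse Kaplan-Meier censoring survival just before their event time
#' (controls share a constant weight, which cancels). With no censoring
#' this reduces exactly to the rank-sum AUC of the event-by-horizon
#' indicator.
#'
#' @param times observed times.
#' @param events 0/1 event indicators.
#' @param scores risk scores (higher = higher risk).
#' @param horizon evaluation time (same units as `times`), before the last
#'   observed time.
#' @param nBoot bootstrap draws for the percentile CI (0 = none).
#' @param seed bootstrap seed.
#' @param confLevel CI level.
#' @return A list: `auc`, `n_cases`, `n_controls`, and `ci` when requested.
#' @export
tdAUC <- function(times, events, scores, horizon, nBoot = 0L, seed = 1L,
                  confLevel = 0.95) {
  stopIfNot(horizon < max(times), "horizon must precede the last observed time")
  core <- function(times, events, scores) {
    case <- times <= horizon & events == 1
    ctrl <- times > horizon
    if (!any(case) || !any(ctrl))
      stop("no cases or no controls at the horizon", call. = FALSE)
    Gm <- censoringSurvMinus(times, events)
    g <- Gm(times[case])
    g <- pmax(g, min(g[g > 0], 1))      # guard against zero-weight blowup
    w <- 1 / g
    sc <- scores[case]; su <- scores[ctrl]
    cmp <- outer(sc, su, function(a, b) (a > b) + 0.5 * (a == b))
    sum(w * rowSums(cmp)) / (sum(w) * length(su))
  }
  out <- list(auc = core(times, events, scores),
              n_cases = sum(times <= horizon & events == 1),
              n_controls = sum(times > horizon))
  if (nBoot > 0L) {
    out$ci <- bootCI(function(idx) core(times[idx], events[idx], scores[idx]),
                     length(times), nBoot, seed, confLevel)
  }
  out
}

# Coerce character/logical covariates to factors with declared reference.
prepCovariates <- function(records, covariates) {
  d <- records[, covariates, drop = FALSE]
  for (nm in names(d)) {
    if (is.character(d[[nm]]) || is.logical(d[[nm]]))
      d[[nm]] <- factor(d[[nm]])
  }
  d
}

lrPvalue <- function(fit) {
  ll <- fit$loglik
  stats::pchisq(2 * (ll[2] - ll[1]), sum(!is.na(stats::coef(fit))),
                lower.tail = FALSE)
}

#' Univariate or multivariable Cox hazard-ratio table
#'
#' Reports per-covariate hazard ratios with 95% Wald intervals and
#' likelihood-ratio p-values (per fitted model in univariate mode; per
#' dropped term in multivariable mode). Categorical covariates are
#' expanded against their first (reference) level. A covariate whose fit
#' fails or does not converge is flagged rather than raising an error.
#'
#' @param records cohort table with outcomes and covariates.
#' @param covariates character vector of covariate column names.
#' @param endpoint `"OS"` or `"DFS"`.
#' @param mode `"univariate"` or `"multivariable"`.
#' @return A data.frame: `covariate`, `level`, `hr`, `lo`, `hi`, `p`,
#'   `flag`.
#' @export
coxTable <- function(records, covariates, endpoint = "OS",
                     mode = c("univariate", "multivariable")) {
  mode <- match.arg(mode)
  cols <- endpointCols(endpoint)
  y <- survival::Surv(records[[cols["time"]]], records[[cols["event"]]])
  d <- prepCovariates(records, covariates)

  rowsFor <- function(fit, term, pTerm) {
    cf <- stats::coef(fit)
    keep <- grep(paste0("^", term), names(cf))
    se <- sqrt(diag(fit$var))[keep]
    data.frame(covariate = term,
               level = sub(paste0("^", term), "", names(cf)[keep]),
               hr = exp(cf[keep]),
               lo = exp(cf[keep] - 1.96 * se),
               hi = exp(cf[keep] + 1.96 * se),
               p = pTerm, flag = "", row.names = NULL,
               stringsAsFactors = FALSE)
  }
  flagged <- function(term, why)
    data.frame(covariate = term, level = "", hr = NA_real_, lo = NA_real_,
               hi = NA_real_, p = NA_real_, flag = why,
               stringsAsFactors = FALSE)

  if (mode == "univariate") {
    out <- lapply(covariates, function(term) {
      x <- d[[term]]
      if (length(unique(x[!is.na(x)])) < 2L)
        return(flagged(term, "constant"))
      fit2 <- tryCatch(
        survival::coxph(stats::as.formula(paste("y ~", term)), data = d,
                        ties = "efron"),
        error = function(e) NULL)
      if (is.null(fit2) || any(!is.finite(stats::coef(fit2))) ||
          any(abs(stats::coef(fit2)) > 50, na.rm = TRUE))
        return(flagged(term, "non-convergence"))
      rowsFor(fit2, term, lrPvalue(fit2))
    })
    do.call(rbind, out)
  } else {
    usable <- covariates[vapply(covariates, function(term)
      length(unique(d[[term]][!is.na(d[[term]])])) >= 2L, logical(1))]
    fml <- stats::as.formula(paste("y ~", paste(usable, collapse = " + ")))
    fit <- survival::coxph(fml, data = d, ties = "efron")
    dr <- tryCatch(stats::drop1(fit, test = "Chisq"), error = function(e) NULL)
    out <- lapply(covariates, function(term) {
      if (!term %in% usable) return(flagged(term, "constant"))
      cf <- stats::coef(fit)
      keep <- grep(paste0("^", term), names(cf))
      if (!length(keep) || any(!is.finite(cf[keep])) ||
          any(abs(cf[keep]) > 50))
        return(flagged(term, "non-convergence"))
      pTerm <- if (!is.null(dr) && term %in% rownames(dr))
        dr[term, "Pr(>Chi)"] else NA_real_
      rowsFor(fit, term, pTerm)
    })
    do.call(rbind, out)
  }
}

#' Clinical baseline survival model
#'
#' Multivariable Cox proportional-hazards model on the standard
#' clinicopathological predictors (FIGO stage, histology, vaginal margin,
#' parametrial invasion, LN metastasis, positive LN count, LVSI, tumor
#' size). Constant covariates are dropped with a flag. The fitted linear
#' predictor serves as the comparison risk score for [harrellC()] and
#' [tdAUC()].
#'
#' @param records training cohort table.
#' @param endpoint `"OS"` or `"DFS"`.
#' @param covariates covariate column names.
#' @return A list of class `"BaselineModel"`: `fit`, `covariates`,
#'   `dropped`, `endpoint`.
#' @export
baselineModel <- function(records, endpoint = "OS",
                          covariates = c("figo_stage", "histology",
                                         "margin_positive",
                                         "parametrial_invasion",
                                         "ln_metastasis", "ln_positive_count",
                                         "lvsi", "tumor_size_cm")) {
  cols <- endpointCols(endpoint)
  d <- prepCovariates(records, covariates)
  usable <- covariates[vapply(covariates, function(nm)
    length(unique(d[[nm]][!is.na(d[[nm]])])) >= 2L, logical(1))]
  stopIfNot(length(usable) >= 1L, "no usable baseline covariates")
  d$.time <- records[[cols["time"]]]
  d$.event <- records[[cols["event"]]]
  fml <- stats::as.formula(
    paste("survival::Surv(.time, .event) ~", paste(sort(usable), collapse = " + ")))
  fit <- survival::coxph(fml, data = d, ties = "efron")
  structure(list(fit = fit, covariates = sort(usable),
                 dropped = setdiff(covariates, usable), endpoint = endpoint),
            class = "BaselineModel")
}

#' Linear predictor of a baseline model on (new) patients
#'
#' @param model a [baselineModel()] result.
#' @param records cohort table containing the model's covariates.
#' @return Numeric risk scores (Cox linear predictor, centered as fitted).
#' @export
predictBaseline <- function(model, records) {
  d <- prepCovariates(records, model$covariates)
  for (nm in names(d)) {
    if (is.factor(d[[nm]])) {
      tr <- model$fit$xlevels[[nm]]
      if (!is.null(tr)) d[[nm]] <- factor(as.character(d[[nm]]), levels = tr)
    }
  }
  unname(stats::predict(model$fit, newdata = d, type = "lp"))
}

#' Clinicopathological risk status
#'
#' High risk: any of LN metastasis, parametrial invasion, or positive
#' vaginal margin, or at least two intermediate factors (LVSI, deep
#' stromal invasion > 1/2, tumor size > 4 cm). Low risk: no high-risk
#' factor and at most one intermediate factor.
#'
#' @param records cohort table with `ln_metastasis`, `parametrial_invasion`,
#'   `margin_positive`, `lvsi`, `dsi_deep`, `tumor_size_cm`.
#' @return Character vector, `"high"` or `"low"` per patient.
#' @export
clinicalRiskStatus <- function(records) {
  highFactor <- records$ln_metastasis == 1 |
    records$parametrial_invasion == 1 | records$margin_positive == 1
  intermediate <- (records$lvsi == 1) + (records$dsi_deep == 1) +
    (records$tumor_size_cm > 4)
  ifelse(highFactor | intermediate >= 2, "high", "low")
}

#' Positive-lymph-node count groups
#'
#' @param count integer vector of positive LN counts.
#' @return Factor with levels `"0"`, `"1-2"`, `">2"`.
#' @export
lnCountGroup <- function(count) {
  cut(count, c(-Inf, 0, 2, Inf), labels = c("0", "1-2", ">2"))
}

#' Per-stratum Kaplan-Meier / log-rank comparison of RS groups
#'
#' Within each stratum (FIGO stage, clinical risk status, LN-count group,
#' or any supplied labeling), compares high- vs low-RS patients — assigned
#' by the global training cutpoint — with the log-rank test. Strata with
#' fewer than 2 patients in either RS group are reported as not evaluable.
#'
#' @param rs data.frame from [applyRiskModel()] (`patient_id`, `group`).
#' @param records outcome table (matched by `patient_id`).
#' @param strata vector of stratum labels, one per row of `rs`.
#' @param endpoint `"OS"` or `"DFS"`.
#' @return A data.frame: `stratum`, `n`, `n_high`, `n_low`, `chisq`, `p`,
#'   `evaluable`.
#' @export
subgroupKM <- function(rs, records, strata, endpoint = "OS") {
  stopIfNot(length(strata) == nrow(rs), "one stratum label per patient")
  records <- records[match(rs$patient_id, records$patient_id), ]
  cols <- endpointCols(endpoint)
  out <- lapply(unique(as.character(strata)), function(s) {
    idx <- as.character(strata) == s
    g <- rs$group[idx]
    nHigh <- sum(g == "high"); nLow <- sum(g == "low")
    if (nHigh < 2L || nLow < 2L)
      return(data.frame(stratum = s, n = sum(idx), n_high = nHigh,
                        n_low = nLow, chisq = NA_real_, p = NA_real_,
                        evaluable = FALSE))
    lr <- tryCatch(
      logrankTest(records[[cols["time"]]][idx],
                  records[[cols["event"]]][idx], g),
      error = function(e) NULL)
    if (is.null(lr))
      return(data.frame(stratum = s, n = sum(idx), n_high = nHigh,
                        n_low = nLow, chisq = NA_real_, p = NA_real_,
                        evaluable = FALSE))
    data.frame(stratum = s, n = sum(idx), n_high = nHigh, n_low = nLow,
               chisq = lr$chisq, p = lr$p, evaluable = TRUE)
  })
  do.call(rbind, out)
}

check2x2 <- function(tab) {
  tab <- as.matrix(tab)
  stopIfNot(all(dim(tab) == c(2L, 2L)), "a 2x2 table is required")
  stopIfNot(all(tab >= 0) && all(tab == round(tab)),
            "counts must be nonnegative integers")
  tab
}

#' Fisher's exact test for a 2x2 table (two-sided)
#'
#' Two-sided p by the probability-ordering convention: the sum of
#' hypergeometric probabilities of all tables with the observed margins no
#' more probable than the observed one. A zero margin yields `p = 1` with
#' a flag (the table carries no information).
#'
#' @param tab 2x2 matrix of nonnegative integer counts.
#' @return A list: `p`, `flag` (`""` or `"zero-margin"`).
#' @examples
#' fisherExact2x2(matrix(c(7, 3, 49, 3), 2, byrow = TRUE))$p  # 0.048
#' @export
fisherExact2x2 <- function(tab) {
  tab <- check2x2(tab)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    return(list(p = 1, flag = "zero-margin"))
  list(p = stats::fisher.test(tab)$p.value, flag = "")
}

#' Continuity-corrected chi-square test for a 2x2 table
#'
#' Pearson chi-square with the Yates continuity correction on 1 degree of
#' freedom. Refuses tables with any expected count below 5 and directs the
#' caller to [fisherExact2x2()].
#'
#' @param tab 2x2 matrix of nonnegative integer counts.
#' @return A list: `chisq`, `p`.
#' @export
chisqYates2x2 <- function(tab) {
  tab <- check2x2(tab)
  expd <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stopIfNot(all(expd >= 5),
            "expected count below 5: use fisherExact2x2() instead")
  ct <- stats::chisq.test(tab, correct = TRUE)
  list(chisq = unname(ct$statistic), p = ct$p.value)
}

#' Categorical association test with the cohort-characteristics rule
#'
#' The test-selection rule used for cohort characteristics tables: for a
#' 2x2 table, Fisher's exact test when any expected count is below 5,
#' otherwise the continuity-corrected chi-square; for larger tables,
#' Fisher's exact test with a seeded Monte-Carlo fallback (1e5 draws) when
#' exact enumeration is infeasible.
#'
#' @param tab r x c matrix of counts.
#' @param seed seed for the Monte-Carlo fallback.
#' @return A list: `p`, `method`.
#' @export
table1Test <- function(tab, seed = 1L) {
  tab <- as.matrix(tab)
  if (all(dim(tab) == c(2L, 2L))) {
    expd <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(expd < 5)) {
      list(p = fisherExact2x2(tab)$p, method = "fisher")
    } else {
      list(p = chisqYates2x2(tab)$p, method = "chisq-yates")
    }
  } else {
    p <- tryCatch(stats::fisher.test(tab)$p.value, error = function(e) {
      set.seed(seed)
      stats::fisher.test(tab, simulate.p.value = TRUE, B = 1e5)$p.value
    })
    list(p = p, method = "fisher")
  }
}

#' Evaluate a risk score on one cohort and endpoint
#'
#' Computes the full report for one endpoint/cohort: Harrell's C with
#' bootstrap CI, time-dependent AUC at the requested horizons,
#' Kaplan-Meier curves per RS group, and the two-group log-rank test.
#'
#' @param rs data.frame from [applyRiskModel()] for the cohort.
#' @param records outcome table for the same patients.
#' @param endpoint `"OS"` or `"DFS"`.
#' @param horizons AUC horizons in months (default 36 and 60: the 3- and
#'   5-year operating points).
#' @param nBoot bootstrap draws for CIs.
#' @param seed bootstrap seed.
#' @return A list of class `"EvalReport"`.
#' @export
evalReport <- function(rs, records, endpoint = "OS", horizons = c(36, 60),
                       nBoot = 200L, seed = 1L) {
  records <- records[match(rs$patient_id, records$patient_id), ]
  cols <- endpointCols(endpoint)
  time <- records[[cols["time"]]]
  event <- records[[cols["event"]]]
  cidx <- harrellC(time, event, rs$score, nBoot = nBoot, seed = seed)
  aucs <- lapply(horizons, function(h)
    tryCatch(tdAUC(time, event, rs$score, h, nBoot = nBoot, seed = seed),
             error = function(e) list(auc = NA_real_, error = conditionMessage(e))))
  names(aucs) <- paste0("month", horizons)
  km <- lapply(split(seq_along(time), rs$group), function(idx)
    kmEstimate(time[idx], event[idx])$table)
  lr <- if (length(unique(rs$group)) >= 2L)
    logrankTest(time, event, rs$group)
  else list(chisq = NA_real_, df = NA_integer_, p = NA_real_)
  structure(list(endpoint = endpoint, cIndex = cidx, aucAt = aucs,
                 kmCurves = km, logrank = lr, n = length(time),
                 nEvents = sum(event)),
            class = "EvalReport")
}
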