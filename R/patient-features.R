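#' Aggregate a patient's DE features to one patient-level vector
#'
#' Patient-level DE (PDE) features are the arithmetic mean of the patient's
#' patch codes, taken per dimension; the operation is invariant to patch
#' order.
#'
#' @param de a [DEFeatureSet-class] (or numeric matrix with patches as rows).
#' @return A named numeric vector of length 128 (`de_000` ... `de_127`).
#' @export
aggregatePatient <- function(de) {
  m <- if (is(de, "DEFeatureSet")) featureMatrix(de) else as.matrix(de)
  stopIfNot(nrow(m) >= 1L, "at least one patch row required")
  setNames(colMeans(m), sprintf("de_%03d", seq_len(ncol(m)) - 1L))
}

#' Assemble the patient-by-PDE matrix for a cohort
#'
#' @param deSets list of [DEFeatureSet-class], one per patient.
#' @return A matrix with one row per patient (rownames = patient ids) and
#'   128 named columns.
#' @export
pdeMatrix <- function(deSets) {
  m <- t(vapply(deSets, aggregatePatient, numeric(128L)))
  rownames(m) <- vapply(deSets, patientId, character(1))
  m
}

#' Stratified 3:1 train/test cohort split
#'
#' Randomly splits patients into training and testing cohorts at the target
#' ratio, stratified on an event flag so that rare events are represented
#' in both cohorts proportionally (with roughly 10% events an unstratified
#' split can starve the test cohort of events entirely). Within each
#' stratum the training share is `round(ratio/(ratio+1) * n)`, so cohort
#' sizes are within one patient of the target per stratum. A stratum with
#' fewer than 2 patients is merged into the larger stratum with a warning.
#'
#' @param records cohort data.frame (see [simulateCohort()]).
#' @param ratio training:testing ratio (default 3).
#' @param seed integer seed.
#' @param stratifyOn column name of the 0/1 event flag used for
#'   stratification (default `"os_event"`); `NULL` for no stratification.
#' @return A list of class `"CohortSplit"`: `trainIds`, `testIds`, `ratio`,
#'   `seed`, `stratifyOn`.
#' @export
splitCohort <- function(records, ratio = 3, seed = 1L,
                        stratifyOn = "os_event") {
  stopIfNot(nrow(records) >= 4L, "need at least 4 patients to split")
  set.seed(seed)
  ids <- records$patient_id
  strata <- if (is.null(stratifyOn)) rep(0L, length(ids))
            else records[[stratifyOn]]
  tab <- table(strata)
  if (any(tab < 2L) && length(tab) > 1L) {
    warning("stratum with < 2 patients merged into the largest stratum",
            call. = FALSE)
    small <- names(tab)[tab < 2L]
    strata[strata %in% small] <- names(tab)[which.max(tab)]
  }
  trainFrac <- ratio / (ratio + 1)
  # largest-remainder apportionment: per-stratum training counts sum to
  # round(trainFrac * n), each within one patient of the stratum target
  lv <- unique(strata)
  nS <- vapply(lv, function(s) sum(strata == s), integer(1))
  base <- floor(trainFrac * nS)
  extra <- round(trainFrac * length(ids)) - sum(base)
  if (extra > 0) {
    give <- order(-(trainFrac * nS - base))[seq_len(extra)]
    base[give] <- base[give] + 1L
  }
  k <- pmax(1L, pmin(nS - 1L, base))
  trainIds <- character()
  for (i in seq_along(lv))
    trainIds <- c(trainIds, sample(ids[strata == lv[i]], k[i]))
  structure(list(trainIds = sort(trainIds),
                 testIds = sort(setdiff(ids, trainIds)),
                 ratio = ratio, seed = as.integer(seed),
                 stratifyOn = stratifyOn),
            class = "CohortSplit")
}
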