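#' @importFrom stats rnorm runif rbinom quantile sd var median setNames
#' @importFrom utils head write.csv read.csv
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

#' Derive a stage seed from a global seed
#'
#' Pipeline stages draw their randomness from seeds derived from a single
#' global seed so that any stage can be rerun in isolation with identical
#' results. The derivation is `(seed * 97 + stage index) mod (2^31 - 1)`.
#'
#' @param seed integer global seed.
#' @param stage character stage name, one of the pipeline stages.
#' @return An integer seed.
#' @export
deriveSeed <- function(seed, stage) {
  stages <- c(simulate = 1L, prep = 2L, features = 3L, ae = 4L,
              aggregate = 5L, split = 6L, select = 7L, fit = 8L,
              evaluate = 9L)
  stopIfNot(stage %in% names(stages), "unknown pipeline stage")
  as.integer((as.numeric(seed) * 97 + stages[[stage]]) %% (2^31 - 1))
}

# Validate a survival cohort data.frame (one row per patient).
checkCohort <- function(records) {
  need <- c("patient_id", "os_time", "os_event", "dfs_time", "dfs_event")
  miss <- setdiff(need, names(records))
  stopIfNot(length(miss) == 0L,
            paste("cohort table lacks columns:", paste(miss, collapse = ", ")))
  stopIfNot(all(records$os_time > 0) && all(records$dfs_time > 0),
            "survival times must be positive")
  stopIfNot(all(records$os_event %in% 0:1) && all(records$dfs_event %in% 0:1),
            "event flags must be 0/1")
  stopIfNot(all(records$dfs_time <= records$os_time + 1e-9),
            "dfs_time must not exceed os_time")
  invisible(records)
}

# Column pair (time, event) for an endpoint.
endpointCols <- function(endpoint) {
  endpoint <- match.arg(toupper(endpoint), c("OS", "DFS"))
  if (endpoint == "OS") c(time = "os_time", event = "os_event")
  else c(time = "dfs_time", event = "dfs_event")
}
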