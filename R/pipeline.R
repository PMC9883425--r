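#' Declarative pipeline configuration
#'
#' Collects every stage parameter and the global seed. Stage-level seeds
#' are derived from the global seed with [deriveSeed()], so stages can be
#' rerun in isolation and the whole run is reproducible bit-for-bit under
#' the surrogate backbone.
#'
#' @param outDir run directory for models, scores, reports and manifest.
#' @param seed global integer seed.
#' @param input list: `mode` (`"simulate"`, `"features"`, or `"images"`)
#'   and, for the file-backed modes, `dir` (cohort.csv plus features/ or
#'   PNG slides and `_mask.png` masks).
#' @param simulate list passed to [simulateCohort()] in simulate mode
#'   (`nPatients`, `patchesPerPatient`, plus [groundTruth()] overrides).
#' @param endpoints endpoints to model (`"OS"`, `"DFS"`).
#' @param patchSize,stride,minRoiFraction tiling parameters (images mode).
#' @param referencePatient patient whose first tissue patch anchors stain
#'   normalization (default: first patient); recorded in the manifest.
#' @param aeSpec list of [autoencoderSpec()] overrides (e.g. `epochs`).
#' @param nRepeats stability-selection repeats.
#' @param enetParams elastic-net settings (`alpha`, `nfolds`).
#' @param exactCount exact selected-feature count override (default NULL:
#'   top 15%).
#' @param splitRatio training:testing ratio.
#' @param stratifyOn event flag used to stratify the split.
#' @param minGroupFraction cutpoint group-size bound.
#' @param horizons AUC horizons (months).
#' @param nBoot bootstrap draws for evaluation CIs.
#' @param saveModel write the autoencoder checkpoint JSON (large).
#' @return A list of class `"PipelineConfig"`.
#' @export
pipelineConfig <- function(outDir = "pathRS-run", seed = 1L,
                           input = list(mode = "simulate"),
                           simulate = list(nPatients = 251L,
                                           patchesPerPatient = c(8L, 16L)),
                           endpoints = c("OS", "DFS"),
                           patchSize = 512L, stride = patchSize,
                           minRoiFraction = 0.5, referencePatient = NULL,
                           aeSpec = list(), nRepeats = 1000L,
                           enetParams = list(alpha = 0.5, nfolds = 5L),
                           exactCount = NULL, splitRatio = 3,
                           stratifyOn = "os_event", minGroupFraction = 0.10,
                           horizons = c(36, 60), nBoot = 200L,
                           saveModel = FALSE) {
  structure(list(outDir = outDir, seed = as.integer(seed), input = input,
                 simulate = simulate, endpoints = endpoints,
                 patchSize = as.integer(patchSize), stride = as.integer(stride),
                 minRoiFraction = minRoiFraction,
                 referencePatient = referencePatient, aeSpec = aeSpec,
                 nRepeats = as.integer(nRepeats), enetParams = enetParams,
                 exactCount = exactCount, splitRatio = splitRatio,
                 stratifyOn = stratifyOn,
                 minGroupFraction = minGroupFraction, horizons = horizons,
                 nBoot = as.integer(nBoot), saveModel = isTRUE(saveModel)),
            class = "PipelineConfig")
}

#' Write / read a pipeline configuration as YAML
#'
#' @param config a [pipelineConfig()].
#' @param path YAML path.
#' @return `writePipelineConfig`: invisibly `path`;
#'   `readPipelineConfig`: the restored config.
#' @export
writePipelineConfig <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname writePipelineConfig
#' @export
readPipelineConfig <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(pipelineConfig, x[setdiff(names(x), character())])
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

loadImageCohort <- function(config) {
  dir <- config$input$dir
  records <- checkCohort(read.csv(file.path(dir, "cohort.csv"),
                                  stringsAsFactors = FALSE))
  backbone <- surrogateBackbone(deriveSeed(config$seed, "features"))
  refId <- config$referencePatient %||% records$patient_id[1]
  profile <- NULL
  features <- vector("list", nrow(records))
  for (i in seq_len(nrow(records))) {
    id <- records$patient_id[i]
    imgPath <- file.path(dir, paste0(id, ".png"))
    maskPath <- file.path(dir, paste0(id, "_mask.png"))
    stopIfNot(file.exists(imgPath), paste("missing slide image:", imgPath))
    stopIfNot(file.exists(maskPath), paste("missing ROI mask:", maskPath))
  }
  # stain reference: first tissue patch of the reference patient
  refImg <- readSlideImage(file.path(dir, paste0(refId, ".png")))
  refMask <- readMask(file.path(dir, paste0(refId, "_mask.png")))
  refGrid <- tileROI(refImg, refMask, config$patchSize, config$stride,
                     config$minRoiFraction)
  stopIfNot(nrow(refGrid) > 0, "reference patient has no tissue patches")
  profile <- fitStainReference(extractPatches(refImg, refGrid)[[1]])
  for (i in seq_len(nrow(records))) {
    id <- records$patient_id[i]
    img <- readSlideImage(file.path(dir, paste0(id, ".png")))
    mask <- readMask(file.path(dir, paste0(id, "_mask.png")))
    grid <- tileROI(img, mask, config$patchSize, config$stride,
                    config$minRoiFraction)
    stopIfNot(nrow(grid) > 0, paste("no tissue patches for patient", id))
    patches <- lapply(extractPatches(img, grid), normalizePatch,
                      profile = profile)
    features[[i]] <- extractFeatures(patches, backbone, id)
  }
  list(records = records, features = features, profile = profile)
}

loadFeatureCohort <- function(config) {
  dir <- config$input$dir
  records <- checkCohort(read.csv(file.path(dir, "cohort.csv"),
                                  stringsAsFactors = FALSE))
  features <- lapply(records$patient_id, function(id) {
    p <- file.path(dir, "features", paste0(id, ".csv"))
    stopIfNot(file.exists(p), paste("missing feature file:", p))
    PatchFeatureSet(id, as.matrix(read.csv(p)), "precomputed")
  })
  list(records = records, features = features)
}

#' Run the whole risk-score pipeline
#'
#' Executes the stages in order — input (simulate / load features / tile +
#' normalize + featurize images), autoencoder training, per-patch encoding,
#' patient-level aggregation, cohort split, and per endpoint: stability
#' selection, signature + cutpoint fitting, scoring, and evaluation — and
#' writes scores (CSV), models (JSON), evaluation reports (JSON) and a run
#' manifest to the run directory. A failed stage halts with the stage name;
#' outputs written so far are retained.
#'
#' @param config a [pipelineConfig()].
#' @return Invisibly, a list: `records`, `pde`, `split`, and per-endpoint
#'   `models`, `scores`, `reports` (train/test [evalReport()]s plus the
#'   baseline-model comparison).
#' @export
runPipeline <- function(config) {
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed

  cohort <- stage("input", switch(
    config$input$mode %||% "simulate",
    simulate = {
      sim <- config$simulate
      truthArgs <- sim[setdiff(names(sim), c("nPatients", "patchesPerPatient"))]
      simulateCohort(sim$nPatients %||% 251L,
                     sim$patchesPerPatient %||% c(8L, 16L),
                     truth = do.call(groundTruth, truthArgs),
                     seed = deriveSeed(seed, "simulate"))
    },
    features = loadFeatureCohort(config),
    images = loadImageCohort(config),
    stop("unknown input mode")))
  records <- cohort$records

  aeArgs <- config$aeSpec
  aeArgs$seed <- aeArgs$seed %||% deriveSeed(seed, "ae")
  spec <- do.call(autoencoderSpec, aeArgs)
  ae <- stage("ae", {
    ds <- buildAEDataset(cohort$features, spec$trainFractionPerPatient,
                         spec$valFraction, seed = spec$seed)
    trainAutoencoder(ds$train, ds$validation, spec)
  })
  utils::write.csv(ae@history, file.path(config$outDir, "ae_history.csv"),
                   row.names = FALSE)
  if (config$saveModel)
    writeAutoencoder(ae, file.path(config$outDir, "autoencoder.json"))

  pde <- stage("aggregate", {
    deSets <- lapply(cohort$features, encodeFeatures, model = ae)
    pdeMatrix(deSets)
  })
  utils::write.csv(data.frame(patient_id = rownames(pde), pde,
                              check.names = FALSE),
                   file.path(config$outDir, "pde.csv"), row.names = FALSE)

  split <- stage("split",
    splitCohort(records, ratio = config$splitRatio,
                seed = deriveSeed(seed, "split"),
                stratifyOn = config$stratifyOn))

  trIdx <- rownames(pde) %in% split$trainIds
  recTr <- records[match(rownames(pde)[trIdx], records$patient_id), ]
  recTe <- records[match(rownames(pde)[!trIdx], records$patient_id), ]

  out <- list(records = records, pde = pde, split = split, ae = ae,
              models = list(), scores = list(), reports = list())
  for (k in seq_along(config$endpoints)) {
    ep <- config$endpoints[k]
    sel <- stage("select",
      stabilitySelect(pde[trIdx, , drop = FALSE], recTr, endpoint = ep,
                      nRepeats = config$nRepeats,
                      enetParams = config$enetParams,
                      exactCount = config$exactCount,
                      seed = deriveSeed(seed, "select") + k))
    model <- stage("fit",
      fitRiskModel(pde[trIdx, , drop = FALSE], recTr, selectedIdx(sel),
                   endpoint = ep,
                   minGroupFraction = config$minGroupFraction,
                   onSeparation = "drop"))
    rsAll <- applyRiskModel(model, pde)
    rsTr <- rsAll[trIdx, ]; rsTe <- rsAll[!trIdx, ]

    reports <- stage("evaluate", {
      base <- baselineModel(recTr, endpoint = ep)
      cols <- endpointCols(ep)
      baseTest <- harrellC(recTe[[cols["time"]]], recTe[[cols["event"]]],
                           predictBaseline(base, recTe))
      list(train = evalReport(rsTr, recTr, ep, config$horizons,
                              config$nBoot, deriveSeed(seed, "evaluate")),
           test = evalReport(rsTe, recTe, ep, config$horizons,
                             config$nBoot, deriveSeed(seed, "evaluate")),
           baselineTestC = baseTest$c)
    })

    tag <- tolower(ep)
    utils::write.csv(rsAll, file.path(config$outDir,
                                      paste0("scores_", tag, ".csv")),
                     row.names = FALSE)
    writeRiskModel(model, file.path(config$outDir,
                                    paste0("risk_model_", tag, ".json")))
    jsonlite::write_json(
      list(endpoint = ep,
           c_index = list(train = reports$train$cIndex$c,
                          test = reports$test$cIndex$c,
                          baseline_test = reports$baselineTestC),
           auc = lapply(reports$test$aucAt, `[[`, "auc"),
           logrank = reports$test$logrank,
           selected = selectedIdx(sel),
           frequency = selectionFrequency(sel)),
      file.path(config$outDir, paste0("report_", tag, ".json")),
      digits = NA, auto_unbox = TRUE)

    out$models[[ep]] <- model
    out$scores[[ep]] <- rsAll
    out$reports[[ep]] <- reports
  }

  cfgPath <- writePipelineConfig(config, file.path(config$outDir,
                                                   "config.yaml"))
  manifest <- list(
    package = "pathRS",
    version = as.character(utils::packageVersion("pathRS")),
    seed = seed,
    stageSeeds = sapply(c("simulate", "prep", "features", "ae", "aggregate",
                          "split", "select", "fit", "evaluate"),
                        deriveSeed, seed = seed),
    referencePatient = config$referencePatient,
    configHash = unname(tools::md5sum(cfgPath)),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  jsonlite::write_json(manifest, file.path(config$outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out)
}

#' Write a self-contained demo dataset and configuration
#'
#' Creates a tiny planted-signal cohort (precomputed patch features +
#' outcomes, written as CSV), three toy slides with ROI masks (PNG) for
#' exercising the tiling/normalization path, and a ready-to-run
#' `config.yaml` sized to finish in minutes on one CPU.
#'
#' @param dir target directory.
#' @param seed integer seed.
#' @return Invisibly, the [pipelineConfig()] written to `dir`.
#' @export
makeDemo <- function(dir = "pathRS-demo", seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- simulateCohort(40L, c(4L, 6L),
                           truth = groundTruth(censorRate = 0.6),
                           seed = seed)
  writeCohort(cohort, file.path(dir, "data"))
  slides <- simulateToySlides(3L, imageSize = 192L, patchSize = 64L,
                              seed = seed)
  writeToySlides(slides, file.path(dir, "slides"))
  config <- pipelineConfig(
    outDir = file.path(dir, "run"), seed = seed,
    input = list(mode = "features", dir = file.path(dir, "data")),
    endpoints = "OS",
    aeSpec = list(epochs = 10L), nRepeats = 25L,
    enetParams = list(alpha = 0.5, nfolds = 3L), exactCount = 4L,
    nBoot = 50L)
  writePipelineConfig(config, file.path(dir, "config.yaml"))
  invisible(config)
}
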