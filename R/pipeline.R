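## End-to-end orchestration: one config object drives simulate -> ROI ->
## radiomics -> autoencoder -> cascade (radiomic / ae / combined modes) ->
## evaluation, with every stage seed derived deterministically from the
## global seed and artifacts written as CSV/JSON when an output directory
## is given.

#' Build a pipeline configuration
#'
#' Returns the default configuration as a named nested list; any element
#' can be overridden via `...` (e.g. `pipelineConfig(seed = 7,
#' cohort = list(nPatients = 12))` — overrides merge recursively).
#'
#' @param ... overrides merged into the defaults.
#' @return A named list with components `cohort`, `roi`, `radiomics`, `ae`,
#'   `selection`, `cascade`, `split`, `seed`, `outputDir`.
#' @export
pipelineConfig <- function(...) {
  cfg <- list(
    seed = 1L,
    outputDir = NULL,
    cohort = list(nPatients = 60, classProportions = c(40, 80, 100) / 220,
                  vesselsPerPatient = 3, viewsPerVessel = 8,
                  missingViewRate = 0.1, imageRows = 854, imageCols = 120,
                  lumenWidthPx = 16, noiseSd = 0.03),
    roi = list(targetRows = 854),
    radiomics = list(nBins = 25),
    ae = list(latentDim = 64, epochs = 300, batchSize = 48, lr = 1e-3,
              validationFraction = 0.2),
    selection = list(rhoMax = 0.95, alpha = 0.05),
    cascade = list(ntree = 500, modes = c("radiomic", "ae", "combined")),
    split = list(testFraction = 0.15, innerRepeats = 0,
                 innerValFraction = 0.2))
  over <- list(...)
  .mergeConfig(cfg, over)
}

.mergeConfig <- function(base, over) {
  for (nm in names(over)) {
    base[[nm]] <- if (is.list(base[[nm]]) && is.list(over[[nm]]))
      .mergeConfig(base[[nm]], over[[nm]]) else over[[nm]]
  }
  base
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; keys mirror [pipelineConfig()].
#' @return Config list (defaults filled in).
#' @export
loadPipelineConfig <- function(path) {
  do.call(pipelineConfig, yaml::read_yaml(path))
}

.configHash <- function(config) {
  s <- paste(deparse(config), collapse = "")
  sprintf("%08x", sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 97 + 1)) %%
            .Machine$integer.max)
}

.logStage <- function(stage, seed, t0, verbose) {
  if (verbose)
    message(sprintf("[%s] stage=%s seed=%s elapsed=%.1fs",
                    format(Sys.time(), "%H:%M:%S"), stage,
                    if (is.null(seed)) "-" else seed,
                    as.numeric(proc.time()[3] - t0)))
}

#' Run the full grading pipeline
#'
#' Generates (or accepts) a cohort, builds the ROI stack, extracts radiomic
#' features, trains the autoencoder on the training patients only (no test
#' leakage), encodes latent features, then for each requested mode
#' (radiomic / ae / combined) fits the cascade on the training pool and
#' evaluates on the held-out test patients.
#'
#' @param config from [pipelineConfig()] / [loadPipelineConfig()].
#' @param cohort optional pre-generated [MPRCohort-class] (skips simulate).
#' @param verbose log stage progress.
#' @return List with `cohort`, `stack`, `features` (per domain), `splits`,
#'   `models`, `predictions`, `reports` (per mode, each an
#'   [EvaluationReport-class]), and `meta` (config, hash, seeds).
#' @export
runPipeline <- function(config = pipelineConfig(), cohort = NULL,
                        verbose = FALSE) {
  t0 <- proc.time()[3]
  seed <- config$seed
  if (is.null(cohort)) {
    spec <- do.call(cohortSpec, c(config$cohort,
                                  seed = .deriveSeed(seed, "cohort")))
    cohort <- generateCohort(spec)
  }
  .logStage("simulate", seed, t0, verbose)
  stack <- buildROIStack(cohort, targetRows = config$roi$targetRows)
  .logStage("roi", NULL, t0, verbose)

  tr <- groundTruth(cohort)
  splits <- makeSplits(tr$patientId, tr$classLabel,
                       testFraction = config$split$testFraction,
                       innerRepeats = config$split$innerRepeats,
                       innerValFraction = config$split$innerValFraction,
                       seed = .deriveSeed(seed, "split"))

  radFs <- radiomicFeatures(stack, nBins = config$radiomics$nBins,
                            verbose = verbose)
  .logStage("radiomics", NULL, t0, verbose)

  trainStack <- subsetPatients(stack, splits$trainPool)
  aeCfg <- aeConfig(config$ae$latentDim,
                    inputDim = prod(roiDims(stack)))
  ae <- buildAE(aeCfg, seed = .deriveSeed(seed, "ae-init"))
  ae <- trainAE(ae, aeInput(trainStack), epochs = config$ae$epochs,
                batchSize = config$ae$batchSize, lr = config$ae$lr,
                validationFraction = config$ae$validationFraction,
                seed = .deriveSeed(seed, "ae-train"), verbose = verbose)
  aeFs <- aeFeatures(ae, stack)
  .logStage("autoencoder", NULL, t0, verbose)

  domains <- list(radiomic = radFs, ae = aeFs,
                  combined = fuseFeatures(radFs, aeFs))
  models <- predictions <- reports <- list()
  for (mode in config$cascade$modes) {
    fs <- domains[[mode]]
    fit <- fitCascade(subsetPatients(fs, splits$trainPool),
                      ntree = config$cascade$ntree,
                      rhoMax = config$selection$rhoMax,
                      alpha = config$selection$alpha,
                      seed = .deriveSeed(seed, paste0("cascade-", mode)))
    pred <- predictPatients(fit, subsetPatients(fs, splits$test))
    models[[mode]] <- fit
    predictions[[mode]] <- pred
    reports[[mode]] <- evaluatePrediction(pred, tr)
    .logStage(paste0("cascade-", mode), NULL, t0, verbose)
  }
  out <- list(cohort = cohort, stack = stack, ae = ae, features = domains,
              splits = splits, models = models, predictions = predictions,
              reports = reports,
              meta = list(config = config, hash = .configHash(config),
                          seed = seed,
                          rVersion = as.character(getRversion())))
  if (!is.null(config$outputDir)) writeArtifacts(out, config$outputDir)
  out
}

#' Write pipeline artifacts to a directory
#'
#' Feature matrix CSVs, the selection reports and patient predictions as
#' JSON/CSV, the evaluation reports, the loss history, the split plan and a
#' run-metadata JSON embedding the config hash.
#'
#' @param result value of [runPipeline()].
#' @param dir output directory.
#' @return The directory, invisibly.
#' @export
writeArtifacts <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (mode in names(result$features)) {
    M <- t(featureValues(result$features[[mode]]))
    write.csv(data.frame(image = rownames(M), M, check.names = FALSE),
              file.path(dir, paste0("features_", mode, ".csv")),
              row.names = FALSE)
  }
  write.csv(result$ae@history, file.path(dir, "ae_loss_history.csv"),
            row.names = FALSE)
  jsonlite::write_json(result$splits, file.path(dir, "splits.json"),
                       auto_unbox = TRUE, digits = NA)
  for (mode in names(result$models)) {
    m <- result$models[[mode]]
    jsonlite::write_json(
      list(stageA = list(selected = m@stageA$features,
                         thresholds = as.list(m@stageA$report@thresholds)),
           stageB = list(selected = m@stageB$features,
                         thresholds = as.list(m@stageB$report@thresholds)),
           seed = m@seed, votePolicy = m@votePolicy),
      file.path(dir, paste0("model_", mode, ".json")), auto_unbox = TRUE)
    write.csv(patientPredictions(result$predictions[[mode]]),
              file.path(dir, paste0("predictions_", mode, ".csv")),
              row.names = FALSE)
    rep <- result$reports[[mode]]
    jsonlite::write_json(
      list(metrics = as.list(evaluationMetrics(rep)),
           confusion = as.data.frame.matrix(confusionMatrix(rep))),
      file.path(dir, paste0("report_", mode, ".json")), auto_unbox = TRUE,
      digits = NA)
  }
  jsonlite::write_json(
    list(hash = result$meta$hash, seed = result$meta$seed,
         rVersion = result$meta$rVersion,
         timestamp = format(Sys.time())),
    file.path(dir, "run_metadata.json"), auto_unbox = TRUE)
  invisible(dir)
}
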