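## End-to-end orchestration: simulate (or load) a cohort, condition the
## signals, detect events, compute the gait parameters and correlation
## matrices, optionally train and evaluate the classifier, and write all
## artifacts plus a reproducibility manifest.

#' Run the full gait assessment pipeline
#'
#' For each subject the pipeline writes the conditioned signals, the
#' stance table, the qualitative and temporal gait-parameter reports and
#' the rendered correlation-matrix images; with `train = TRUE` it also
#' builds the image dataset, trains the classifier and writes its test
#' metrics. A run manifest (config, seed, package version) makes the run
#' reproducible.
#'
#' @param outputDir output directory (created).
#' @param recordings optional list of [GaitRecording-class] or paths to
#'   telemetry files; when `NULL` a cohort is simulated.
#' @param nPerClass simulated subjects per class (when simulating).
#' @param nCycles gait cycles per simulated subject.
#' @param seed run seed.
#' @param train train and evaluate the classifier.
#' @param trainCfg a [trainConfig()]; its seed is overridden by `seed`.
#' @param eventCfg an [eventConfig()].
#' @param consts acquisition constants.
#' @param writeImages write the per-stance matrix images as PNG.
#' @param quiet suppress progress messages.
#' @return Invisibly, a list with the per-subject assessments and (when
#'   trained) the model and test metrics.
#' @export
runPipeline <- function(outputDir, recordings = NULL, nPerClass = 5L,
                        nCycles = 12L, seed = 1L, train = FALSE,
                        trainCfg = trainConfig(), eventCfg = eventConfig(),
                        consts = acquisitionConstants(),
                        writeImages = FALSE, quiet = FALSE) {
  say <- function(...) if (!quiet) message(...)
  dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)

  if (is.null(recordings)) {
    say("simulating ", 2L * nPerClass, "-subject cohort (seed ", seed, ")")
    cohort <- simulateCohort(nPerClass, seed = seed, nCycles = nCycles)
    recs <- lapply(cohort, `[[`, "recording")
  } else {
    recs <- lapply(recordings, function(r)
      if (is.character(r)) readGaitRecording(r, consts) else r)
  }

  assessOne <- function(rec) {
    say("assessing subject ", subjectId(rec))
    space <- buildSignalSpace(rec, consts)
    stL <- detectStances(space, "left", eventCfg)
    stR <- detectStances(space, "right", eventCfg)
    stances <- rbind(stL, stR)
    subjDir <- file.path(outputDir, subjectId(rec))
    dir.create(subjDir, showWarnings = FALSE)
    utils::write.csv(data.frame(t = effectiveTimes(space),
                                signalMatrix(space), check.names = FALSE),
                     file.path(subjDir, "signals.csv"), row.names = FALSE)
    exportStanceTable(stances, file.path(subjDir, "stances.tsv"))
    bio <- biomechProfile(space, eventCfg)
    tmp <- temporalProfile(space, stances, eventCfg)
    rep <- c(utils::capture.output(print(bio)),
             utils::capture.output(print(tmp)))
    writeLines(rep, file.path(subjDir, "assessment.txt"))
    list(space = space, stances = stances, biomech = bio, temporal = tmp)
  }
  assessments <- lapply(recs, assessOne)
  names(assessments) <- vapply(recs, subjectId, "")

  ## cohort-level temporal summary mirroring a cohort report table
  tab <- do.call(rbind, lapply(seq_along(recs), function(i) {
    tp <- assessments[[i]]$temporal
    data.frame(subject = subjectId(recs[[i]]), label = gaitLabel(recs[[i]]),
               cadence_spm = tp$cadence_spm,
               single_left = tp$single_support_pct["left"],
               single_right = tp$single_support_pct["right"],
               double = tp$double_support_pct,
               sd_left = tp$sd_ratio["left"], sd_right = tp$sd_ratio["right"],
               stride_cov = tp$stride_cov_pct)
  }))
  utils::write.csv(tab, file.path(outputDir, "temporal_parameters.csv"),
                   row.names = FALSE)

  result <- list(assessments = assessments, temporal = tab)

  labeled <- vapply(recs, function(r) gaitLabel(r) != "unknown", TRUE)
  if (train && sum(labeled) >= 2L) {
    say("building matrix-image dataset")
    cfg <- trainCfg
    cfg$seed <- as.integer(seed)
    ds <- makeDataset(recs[labeled], consts, eventCfg)
    writeDatasetManifest(ds, file.path(outputDir, "dataset"),
                         writeImages = writeImages)
    split <- splitDataset(ds, cfg)
    trainSet <- if (cfg$augmentFactor > 1L)
      augmentDataset(split$train, cfg$augmentFactor, seed = cfg$seed)
    else split$train
    say("training classifier (", cfg$epochs, " epochs)")
    model <- trainClassifier(trainSet, split$val, cfg)
    pred <- predictClassifier(model, split$test)
    probs <- as.matrix(pred[, 1:2])
    yIdx <- match(split$test$manifest$label, .CLASS_LEVELS)
    losses <- -log(pmax(probs[cbind(seq_len(nrow(probs)), yIdx)], 1e-12))
    metrics <- evaluateMetrics(split$test$manifest$label, pred$label, losses)
    writeLines(jsonlite::toJSON(unclass(metrics), auto_unbox = TRUE,
                                digits = I(6), na = "null"),
               file.path(outputDir, "metrics.json"))
    utils::write.csv(model$history, file.path(outputDir, "history.csv"),
                     row.names = FALSE)
    result$model <- model
    result$metrics <- metrics
  }

  manifest <- list(package = "pdgait",
                   version = as.character(utils::packageVersion("pdgait")),
                   seed = seed, nPerClass = nPerClass, train = train,
                   eventConfig = unclass(eventCfg),
                   trainConfig = lapply(unclass(trainCfg), unclass),
                   timestamp = format(Sys.time(), tz = "UTC"))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE),
             file.path(outputDir, "run_manifest.json"))
  say("done: ", outputDir)
  invisible(result)
}
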