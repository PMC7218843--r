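# End-to-end orchestration: simulate (or load), preprocess, label, extract
# features, run the isolated-classification sanity check, train the
# sequence labeler, predict and evaluate — writing all reports to a run
# directory.

#' Pipeline configuration
#'
#' Nested per-stage sections; every stage's defaults reproduce the study
#' settings (see the stage constructors). All randomness flows from the
#' single global `seed`: per-subject simulation, SVM fold assignment and
#' LSTM training seeds are derived from it.
#'
#' @param seed global integer seed.
#' @param nSubjects number of simulated subjects.
#' @param trainTrialsPerStimulus trials per stimulus used for training; the
#'   remaining trials are the held-out test set.
#' @param sim named list of [simConfig] overrides.
#' @param preprocess a [preprocessConfig].
#' @param labeling a [vadDetectorConfig].
#' @param wienerFirst apply [wienerDenoiseAudio] to the microphone signal
#'   before detection. Off by default: on stationary background noise the
#'   spectral-subtraction residual inflates boundary-energy variance and
#'   degrades onset/offset precision; enable it for recordings with
#'   structured microphone noise.
#' @param svm an [svmConfig].
#' @param lstm an [lstmConfig].
#' @param eval list with `rule` (run-selection for timing errors) and `topK`
#'   (sensor-mode report size).
#' @return list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(seed = 1L, nSubjects = 8L,
                           trainTrialsPerStimulus = 50L, sim = list(),
                           preprocess = preprocessConfig(),
                           labeling = vadDetectorConfig(),
                           wienerFirst = FALSE, svm = svmConfig(),
                           lstm = lstmConfig(),
                           eval = list(rule = "longest", topK = 5L)) {
  structure(list(seed = as.integer(seed), nSubjects = as.integer(nSubjects),
                 trainTrialsPerStimulus = as.integer(trainTrialsPerStimulus),
                 sim = sim, preprocess = preprocess, labeling = labeling,
                 wienerFirst = isTRUE(wienerFirst), svm = svm, lstm = lstm,
                 eval = eval),
            class = "PipelineConfig")
}

writeJson <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = 10,
                       pretty = TRUE, null = "null", na = "null")
}

#' Run the full pipeline
#'
#' Simulates `config$nSubjects` subjects (deterministically from the global
#' seed), preprocesses each session (gradiometer selection, bad-channel
#' removal, robust artifact-trial rejection, wavelet band restriction,
#' production-window extraction), labels each trial from its denoised
#' acoustic channel, extracts segment and framewise features, runs the
#' cross-validated isolated classification, trains the sequence labeler on
#' the first `trainTrialsPerStimulus` kept trials of each stimulus and
#' evaluates per-sample metrics, timing errors and the sensor-mode analysis
#' on the held-out trials. All reports are written under `outDir`.
#'
#' @param config a [pipelineConfig].
#' @param outDir output directory (created if missing).
#' @return invisibly, the summary list (also written as `summary.json`).
#' @export
runPipeline <- function(config = pipelineConfig(), outDir) {
  stopifnot(inherits(config, "PipelineConfig"))
  for (section in c("sim", "preprocess", "labeling", "svm", "lstm", "eval"))
    if (is.null(config[[section]]))
      stop("config missing section '", section, "'")
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  logPath <- file.path(outDir, "log.jsonl")
  if (file.exists(logPath)) unlink(logPath)
  logLine <- function(...) {
    rec <- list(...)
    cat(jsonlite::toJSON(rec, auto_unbox = TRUE), "\n",
        file = logPath, append = TRUE, sep = "")
  }
  tic <- function() proc.time()[["elapsed"]]

  allTrialMetrics <- list()
  allCounts <- list()
  allSubjects <- character()
  svmTables <- list()
  onsetErrs <- list()
  sensorTop <- list()
  labelRows <- list()
  rejRows <- list()
  truthRows <- list()

  for (s in seq_len(config$nSubjects)) {
    subj <- sprintf("S%02d", s)
    t0 <- tic()
    simArgs <- utils::modifyList(config$sim,
                                 list(subjectId = subj,
                                      seed = config$seed * 1000L + s))
    sess <- simulateSession(do.call(simConfig, simArgs))
    truthRows[[s]] <- trialInfo(sess$truth)
    logLine(stage = "simulate", subject = subj,
            trials = nrow(sess$events), elapsed_s = round(tic() - t0, 2))

    t0 <- tic()
    epochs <- selectGradiometers(epochTrials(sess$recording))
    db <- dropBadChannels(epochs, config$preprocess$flatThreshold,
                          config$preprocess$noiseThreshold)
    rj <- rejectArtifactTrials(db$epochs,
                               config$preprocess$artifactZscoreThreshold)
    keptTrials <- setdiff(seq_along(db$epochs), rj$rejected)
    if (nrow(rj$report))
      rejRows[[s]] <- cbind(subject = subj, rj$report)
    prod <- lapply(rj$epochs, function(e)
      extractProductionWindow(waveletDenoise(e, config$preprocess)))
    logLine(stage = "preprocess", subject = subj,
            dropped_channels = nrow(db$dropped),
            rejected_trials = length(rj$rejected),
            elapsed_s = round(tic() - t0, 2))

    t0 <- tic()
    sf <- prod[[1L]]@sfreq
    det <- lapply(prod, function(e) {
      a <- audioSignal(e)
      if (config$wienerFirst) a <- wienerDenoiseAudio(a, sf)
      detectVoiceActivity(a, sf, config$labeling)
    })
    ok <- vapply(det, `[[`, TRUE, "detected")
    if (!any(ok)) stop("stage labeling, subject ", subj,
                       ": no voice detected in any trial")
    prod <- prod[ok]
    keptTrials <- keptTrials[ok]
    labels <- lapply(det[ok], function(d)
      labelSegments(d$onset, d$offset, ncol(prod[[1L]]@data)))
    labelRows[[s]] <- data.frame(subject = subj, trial = keptTrials,
                                 onset_ms = vapply(labels, speechOnset, 1L),
                                 offset_ms = vapply(labels, speechOffset, 1L))
    logLine(stage = "label", subject = subj, labeled = length(labels),
            undetected = sum(!ok), elapsed_s = round(tic() - t0, 2))

    t0 <- tic()
    feats <- lapply(prod, framewiseFeatures)
    segset <- segmentFeatureSet(prod, labels)
    svmCfg <- config$svm
    svmCfg$seed <- config$seed * 1000L + s
    svmTab <- svmIsolatedClassify(segset$features, segset$labels, svmCfg)
    svmTables[[s]] <- cbind(subject = subj, svmTab)
    logLine(stage = "svm", subject = subj,
      speech_vs_nonspeech = svmTab$mean_accuracy[
        svmTab$pairing == "SPEECH-vs-NONSPEECH"],
      elapsed_s = round(tic() - t0, 2))

    t0 <- tic()
    stimIds <- vapply(prod, stimulusId, 1L)
    isTrain <- logical(length(prod))
    for (st in unique(stimIds)) {
      ix <- which(stimIds == st)
      isTrain[utils::head(ix, config$trainTrialsPerStimulus)] <- TRUE
    }
    if (all(isTrain)) stop("no held-out test trials; reduce ",
                           "trainTrialsPerStimulus or simulate more trials")
    lstmCfg <- config$lstm
    lstmCfg$seed <- config$seed * 1000L + s
    model <- trainVadLstm(feats[isTrain], labels[isTrain], lstmCfg)
    saveVadModel(model, file.path(outDir, sprintf("model_%s.rds", subj)))
    logLine(stage = "train", subject = subj, train_trials = sum(isTrain),
            epochs_run = nrow(trainingHistory(model)),
            elapsed_s = round(tic() - t0, 2))

    t0 <- tic()
    testIx <- which(!isTrain)
    preds <- lapply(feats[testIx], function(f) predictSequence(model, f))
    counts <- mapply(function(p, l) confusionCounts(p$labels, labels2(l)),
                     preds, labels[testIx], SIMPLIFY = FALSE)
    errs <- mapply(function(p, l)
      onsetOffsetErrors(p$labels, labels2(l), sf, rule = config$eval$rule),
      preds, labels[testIx], SIMPLIFY = FALSE)
    onsetErrs[[s]] <- data.frame(
      subject = subj, trial = keptTrials[testIx],
      onset_error_ms = vapply(errs, `[[`, 1, "onset_error_ms"),
      offset_error_ms = vapply(errs, `[[`, 1, "offset_error_ms"))
    sm <- sensorModeAnalysis(feats[testIx],
                             lapply(labels[testIx], labels2),
                             topK = config$eval$topK)
    sensorTop[[s]] <- data.frame(subject = subj,
                                 sensor = sm$pooled$sensor,
                                 count = sm$pooled$count)
    allCounts <- c(allCounts, counts)
    allSubjects <- c(allSubjects, rep(subj, length(counts)))
    logLine(stage = "evaluate", subject = subj, test_trials = length(testIx),
            elapsed_s = round(tic() - t0, 2))
  }

  metrics <- vadMetrics(allCounts, allSubjects)
  errTab <- do.call(rbind, onsetErrs)
  summary <- list(
    seed = config$seed,
    n_subjects = config$nSubjects,
    subject_summary = metrics$subjectSummary,
    grand_mean_accuracy = metrics$grandMeanAccuracy,
    pooled = metrics$pooled,
    mean_onset_error_ms = mean(errTab$onset_error_ms, na.rm = TRUE),
    mean_offset_error_ms = mean(errTab$offset_error_ms, na.rm = TRUE))

  utils::write.csv(do.call(rbind, labelRows),
                   file.path(outDir, "labels.csv"), row.names = FALSE)
  if (length(rejRows))
    utils::write.csv(do.call(rbind, rejRows),
                     file.path(outDir, "rejections.csv"), row.names = FALSE)
  utils::write.csv(do.call(rbind, truthRows),
                   file.path(outDir, "ground_truth.csv"), row.names = FALSE)
  utils::write.csv(do.call(rbind, svmTables),
                   file.path(outDir, "svm.csv"), row.names = FALSE)
  utils::write.csv(metrics$trials, file.path(outDir, "trial_metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(errTab, file.path(outDir, "timing_errors.csv"),
                   row.names = FALSE)
  utils::write.csv(do.call(rbind, sensorTop),
                   file.path(outDir, "sensor_counts.csv"), row.names = FALSE)
  writeJson(configAsList(config), file.path(outDir, "config.json"))
  writeJson(summary, file.path(outDir, "summary.json"))
  invisible(summary)
}

configAsList <- function(config) {
  strip <- function(x)
    if (is.list(x)) lapply(unclass(x), strip) else x
  strip(config)
}
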