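# Per-sample metrics, timing-error analysis, sensor-mode analysis and the
# paired one-tailed comparisons.

#' Sample-wise confusion counts
#'
#' Counts with `SPEECH` as the positive class:
#' `accuracy = (TP + TN) / (TP + TN + FP + FN)`.
#'
#' @param pred,truth per-sample binary labels (factors or characters over
#'   SPEECH / NONSPEECH), equal length.
#' @return list of class `ConfusionCounts` with integer `TP`, `TN`, `FP`,
#'   `FN`.
#' @export
confusionCounts <- function(pred, truth) {
  pred <- as.character(pred); truth <- as.character(truth)
  if (length(pred) != length(truth))
    stop("prediction and truth must have equal length")
  p <- pred == "SPEECH"; t <- truth == "SPEECH"
  structure(list(TP = sum(p & t), TN = sum(!p & !t),
                 FP = sum(p & !t), FN = sum(!p & t)),
            class = "ConfusionCounts")
}

#' Metrics from confusion counts
#'
#' Precision is undefined (reported as `NA`, never silently 0) when no
#' positive predictions exist; likewise recall with no positive truth.
#'
#' @param counts a `ConfusionCounts` list (or anything with TP/TN/FP/FN).
#' @return list with `accuracy`, `precision`, `recall`.
#' @export
countMetrics <- function(counts) {
  n <- counts$TP + counts$TN + counts$FP + counts$FN
  list(accuracy = (counts$TP + counts$TN) / n,
       precision = if (counts$TP + counts$FP == 0) NA_real_ else
         counts$TP / (counts$TP + counts$FP),
       recall = if (counts$TP + counts$FN == 0) NA_real_ else
         counts$TP / (counts$TP + counts$FN))
}

#' Aggregate per-trial metrics
#'
#' Per-trial accuracies plus per-subject mean, standard deviation
#' (population formula) and median, and pooled (micro-averaged) precision /
#' recall / accuracy from the summed counts — single pooled values across
#' all trials, as reported across subjects.
#'
#' @param perTrialCounts list of `ConfusionCounts`, one per trial.
#' @param subjects optional character vector of per-trial subject ids.
#' @return list with `trials` (data.frame `trial`, `subject`, `accuracy`),
#'   `subjectSummary` (data.frame `subject`, `mean_accuracy`, `sd_accuracy`,
#'   `median_accuracy`, `n_trials`), `pooled` (micro accuracy / precision /
#'   recall) and `grandMeanAccuracy`.
#' @export
vadMetrics <- function(perTrialCounts, subjects = NULL) {
  if (!length(perTrialCounts)) stop("no trials to evaluate")
  if (is.null(subjects)) subjects <- rep("all", length(perTrialCounts))
  acc <- vapply(perTrialCounts, function(cc) countMetrics(cc)$accuracy,
                numeric(1))
  trials <- data.frame(trial = seq_along(acc), subject = subjects,
                       accuracy = acc)
  popSd <- function(v) sqrt(mean((v - mean(v))^2))
  subjectSummary <- do.call(rbind, lapply(split(acc, subjects), function(a)
    data.frame(mean_accuracy = mean(a), sd_accuracy = popSd(a),
               median_accuracy = stats::median(a), n_trials = length(a))))
  subjectSummary <- cbind(subject = rownames(subjectSummary), subjectSummary)
  rownames(subjectSummary) <- NULL
  pooledCounts <- Reduce(function(a, b)
    list(TP = a$TP + b$TP, TN = a$TN + b$TN, FP = a$FP + b$FP,
         FN = a$FN + b$FN), perTrialCounts)
  list(trials = trials, subjectSummary = subjectSummary,
       pooled = countMetrics(pooledCounts),
       grandMeanAccuracy = mean(subjectSummary$mean_accuracy))
}

speechRuns <- function(lab) {
  runsOf(as.character(lab) == "SPEECH")
}

#' Onset / offset timing errors
#'
#' Signed timing error of the predicted speech interval against the truth,
#' in milliseconds (negative = predicted early). The predicted interval is
#' the *longest* predicted SPEECH run (robust to isolated flipped samples;
#' `rule = "first"` takes the first run instead). Predicted onset follows
#' the labeling convention: the sample before the run's first SPEECH sample.
#'
#' @param pred,truth per-sample binary labels of equal length.
#' @param sfreq sampling rate (Hz).
#' @param rule `"longest"` (default) or `"first"` run selection.
#' @return list with `onset_error_ms`, `offset_error_ms`, `flagged`
#'   (`TRUE`, with `NA` errors, when prediction contains no SPEECH run).
#' @export
onsetOffsetErrors <- function(pred, truth, sfreq,
                              rule = c("longest", "first")) {
  rule <- match.arg(rule)
  pr <- speechRuns(pred)
  tr <- speechRuns(truth)
  if (!nrow(tr)) stop("truth contains no SPEECH run")
  if (!nrow(pr))
    return(list(onset_error_ms = NA_real_, offset_error_ms = NA_real_,
                flagged = TRUE))
  pick <- function(r) if (rule == "longest")
    r[which.max(r$end - r$start), ] else r[1L, ]
  p <- pick(pr); tt <- pick(tr)
  toMs <- 1000 / sfreq
  list(onset_error_ms = ((p$start - 1L) - (tt$start - 1L)) * toMs,
       offset_error_ms = (p$end - tt$end) * toMs,
       flagged = FALSE)
}

#' Sensor-mode analysis of the most-active-sensor feature
#'
#' Frequency (mode) analysis of the sensor-index feature `f4` restricted to
#' speech-labeled samples: counts per sensor, per subject and pooled, and
#' the top-k sensors by pooled count. High counts over speech-related
#' cortex are the expected signature.
#'
#' @param featureSequences list of [FeatureSequence-class] (or T x 4
#'   matrices).
#' @param speechMasks list of logical vectors (or binary label factors)
#'   marking the speech samples of each trial.
#' @param subjects optional per-trial subject ids.
#' @param topK how many top sensors to report.
#' @return list with `pooled` (data.frame `sensor`, `count`, sorted),
#'   `perSubject` (named list of count tables) and `topSensors` (integer).
#' @export
sensorModeAnalysis <- function(featureSequences, speechMasks, subjects = NULL,
                               topK = 5L) {
  stopifnot(length(featureSequences) == length(speechMasks))
  if (is.null(subjects)) subjects <- rep("all", length(featureSequences))
  f4 <- lapply(featureSequences, function(fs)
    if (is(fs, "FeatureSequence")) fs@features[, "f4"] else fs[, 4L])
  masks <- lapply(speechMasks, function(m)
    if (is.logical(m)) m else as.character(m) == "SPEECH")
  sel <- unlist(mapply(function(v, m) v[m], f4, masks, SIMPLIFY = FALSE))
  bySubj <- split(seq_along(f4), subjects)
  perSubject <- lapply(bySubj, function(ix) {
    s <- unlist(mapply(function(v, m) v[m], f4[ix], masks[ix],
                       SIMPLIFY = FALSE))
    sort(table(s), decreasing = TRUE)
  })
  if (!length(sel))
    return(list(pooled = data.frame(sensor = integer(), count = integer()),
                perSubject = perSubject, topSensors = integer()))
  tab <- sort(table(sel), decreasing = TRUE)
  pooled <- data.frame(sensor = as.integer(names(tab)),
                       count = as.integer(tab))
  list(pooled = pooled, perSubject = perSubject,
       topSensors = pooled$sensor[seq_len(min(topK, nrow(pooled)))])
}

#' One-tailed paired t-test
#'
#' Paired t statistic with a one-sided p-value in the requested direction
#' (`"greater"`: mean(a) > mean(b); `"less"`: mean(a) < mean(b)). Identical
#' samples give a zero statistic and p = 0.5; a non-zero mean difference
#' with zero variance is an error.
#'
#' @param a,b equal-length paired samples, n >= 2.
#' @param direction `"greater"` or `"less"`.
#' @return list with `statistic`, `p.value`, `df`.
#' @export
oneTailedPairedTTest <- function(a, b, direction = c("greater", "less")) {
  direction <- match.arg(direction)
  stopifnot(length(a) == length(b), length(a) >= 2L)
  d <- a - b
  if (stats::sd(d) == 0) {
    if (mean(d) == 0)
      return(list(statistic = 0, p.value = 0.5, df = length(d) - 1L))
    stop("zero variance of differences")
  }
  tt <- stats::t.test(a, b, paired = TRUE, alternative = direction)
  list(statistic = unname(tt$statistic), p.value = tt$p.value,
       df = unname(tt$parameter))
}
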