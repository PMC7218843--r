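# Segment-level RMS features (isolated classification) and the four
# framewise features (continuous prediction).

#' Per-sensor RMS features over labeled segments
#'
#' For each requested segment class, the root mean square of every sensor
#' over exactly that class's samples. `NONSPEECH` pools the `PRE` and `POST`
#' samples.
#'
#' @param epoch a [TrialEpoch-class] production window (or sensors x T
#'   matrix).
#' @param labels a [SegmentLabels-class] covering the window (or a factor of
#'   three-way labels).
#' @param classes which segment classes to compute (default all four).
#' @return named list of per-sensor RMS vectors, one per class.
#' @export
segmentRmsFeatures <- function(epoch, labels,
                               classes = c("PRE", "SPEECH", "POST",
                                           "NONSPEECH")) {
  x <- if (is(epoch, "TrialEpoch")) epoch@data else as.matrix(epoch)
  l3 <- if (is(labels, "SegmentLabels")) labels@labels3 else labels
  if (length(l3) != ncol(x))
    stop("labels must cover the epoch's production window")
  out <- lapply(classes, function(cl) {
    idx <- if (cl == "NONSPEECH") which(l3 != "SPEECH") else which(l3 == cl)
    if (!length(idx)) stop("empty segment for class ", cl)
    sqrt(rowMeans(x[, idx, drop = FALSE]^2))
  })
  names(out) <- classes
  out
}

#' Framewise features across sensors
#'
#' At every time point `t`, across the `S` sensors: `f1` the sum of absolute
#' values, `f2` the root mean square, `f3` the cross-sensor standard
#' deviation (population convention, dividing by `S`, so that
#' `f2^2 - f3^2 = mean^2 >= 0` exactly), and `f4` the 1-based index of the
#' sensor with maximum absolute magnitude (ties broken toward the lowest
#' index). `f4` inserts spatial information: sensors over speech-related
#' cortex are expected to dominate during speech.
#'
#' @param epoch a [TrialEpoch-class] or sensors x T numeric matrix with at
#'   least two sensors.
#' @param sfreq sampling rate, required only for matrix input.
#' @return a [FeatureSequence-class] (T x 4).
#' @export
framewiseFeatures <- function(epoch, sfreq = NULL) {
  if (is(epoch, "TrialEpoch")) {
    x <- epoch@data
    sfreq <- epoch@sfreq
  } else {
    x <- as.matrix(epoch)
    if (is.null(sfreq)) stop("sfreq is required for matrix input")
  }
  S <- nrow(x)
  if (S < 2L) stop("at least two sensors are required (std undefined)")
  ax <- abs(x)
  m2 <- colMeans(x^2)
  mu <- colMeans(x)
  feats <- cbind(f1 = colSums(ax),
                 f2 = sqrt(m2),
                 f3 = sqrt(pmax(m2 - mu^2, 0)),
                 f4 = as.numeric(max.col(t(ax), ties.method = "first")))
  new("FeatureSequence", features = feats, sfreq = sfreq,
      nSensors = as.integer(S))
}

#' Standardized difference between the sum-of-absolute and std features
#'
#' `f1` (sum of absolute values) and `f3` (cross-sensor standard deviation)
#' are correlated yet non-redundant; their per-trial standardized difference
#' highlights where they disagree in time. Each feature is z-scored over the
#' trial before subtraction (their raw scales differ by a factor of order
#' `S`); a constant feature standardizes to zero.
#'
#' @param featseq a [FeatureSequence-class].
#' @return numeric length-T vector.
#' @export
featureDifference <- function(featseq) {
  stopifnot(is(featseq, "FeatureSequence"))
  z <- function(v) {
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0) return(numeric(length(v)))
    (v - mean(v)) / s
  }
  z(featseq@features[, "f1"]) - z(featseq@features[, "f3"])
}

#' Model input matrix from a feature sequence
#'
#' Numerical conditioning for the sequence labeler: with
#' `standardize = "trial"` (default), `f1..f3` are z-scored over the trial
#' and the sensor index `f4` is scaled to `[0, 1]` by the sensor count;
#' `"none"` feeds the raw features.
#'
#' @param featseq a [FeatureSequence-class] or T x 4 matrix.
#' @param standardize `"trial"` or `"none"`.
#' @param nSensors sensor count for scaling `f4` (taken from the
#'   [FeatureSequence-class] when available).
#' @return numeric T x 4 matrix.
#' @export
prepareModelInput <- function(featseq, standardize = c("trial", "none"),
                              nSensors = NULL) {
  standardize <- match.arg(standardize)
  if (is(featseq, "FeatureSequence")) {
    m <- featseq@features
    nSensors <- featseq@nSensors
  } else m <- as.matrix(featseq)
  if (standardize == "none") return(m)
  if (is.null(nSensors)) nSensors <- max(m[, 4L])
  z <- function(v) {
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0) v - mean(v) else (v - mean(v)) / s
  }
  cbind(f1 = z(m[, 1L]), f2 = z(m[, 2L]), f3 = z(m[, 3L]),
        f4 = m[, 4L] / nSensors)
}
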