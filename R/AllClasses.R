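#' @import methods
NULL

CHANNEL_KINDS <- c("gradiometer", "magnetometer", "acoustic", "jaw", "eog",
                   "ecg", "other")

#' Continuous multichannel recording
#'
#' A `Recording` holds one continuous session: a sensor-by-sample data matrix,
#' its sampling rate, per-channel names and kinds (gradiometer, magnetometer,
#' acoustic, ...), and the event table of stimulus onsets. The acoustic
#' microphone channel is carried as an ordinary row of `data` tagged with kind
#' `"acoustic"`; labeling workflows require at least one such channel.
#'
#' @slot data numeric matrix, channels in rows, samples in columns.
#' @slot sfreq sampling rate in samples per second.
#' @slot channelNames character vector, one per row of `data`.
#' @slot channelKinds character vector over
#'   `c("gradiometer","magnetometer","acoustic","jaw","eog","ecg","other")`.
#' @slot events data.frame with columns `onset_sample` (1-based sample index),
#'   `stimulus_id`, `subject_id`. Onsets are strictly increasing.
#' @export
setClass("Recording",
  representation(data = "matrix", sfreq = "numeric",
                 channelNames = "character", channelKinds = "character",
                 events = "data.frame"))

setValidity("Recording", function(object) {
  msg <- character()
  if (length(object@sfreq) != 1L || !is.finite(object@sfreq) ||
      object@sfreq <= 0)
    msg <- c(msg, "sfreq must be a single positive number")
  if (nrow(object@data) == 0L)
    msg <- c(msg, "empty channel set")
  if (length(object@channelNames) != nrow(object@data) ||
      length(object@channelKinds) != nrow(object@data))
    msg <- c(msg, "channelNames/channelKinds must match the number of data rows")
  if (!all(object@channelKinds %in% CHANNEL_KINDS))
    msg <- c(msg, paste0("channelKinds must be in {",
                         paste(CHANNEL_KINDS, collapse = ", "), "}"))
  ev <- object@events
  if (nrow(ev) > 0L) {
    need <- c("onset_sample", "stimulus_id", "subject_id")
    if (!all(need %in% names(ev)))
      msg <- c(msg, "events must have columns onset_sample, stimulus_id, subject_id")
    else if (is.unsorted(ev$onset_sample, strictly = TRUE))
      msg <- c(msg, "event onsets must be strictly increasing")
  }
  if (length(msg)) msg else TRUE
})

#' One trial's sensor-by-time epoch
#'
#' A `TrialEpoch` is a fixed window cut from a [Recording] around one stimulus
#' onset. Stage marks locate the protocol stages (stimulus on, preparation
#' cue, production cue, trial end) as 1-based sample indices within the epoch.
#' The synchronized microphone signal is kept in `audio`, aligned sample-wise
#' with the sensor rows.
#'
#' @slot data numeric matrix, sensors x time (acoustic channel excluded).
#' @slot sfreq sampling rate (samples/second).
#' @slot t0Offset time of the first epoch sample relative to stimulus onset,
#'   in seconds (-0.5 for a full protocol epoch; 2.0 for a production window).
#' @slot stageMarks named integer vector with entries `stimulusOn`, `prepCue`,
#'   `productionCue`, `trialEnd` (1-based in-epoch sample indices; `NA` for
#'   marks outside the window).
#' @slot stimulusId integer stimulus identity.
#' @slot audio numeric vector of length `ncol(data)`.
#' @slot channelNames,channelKinds per-row channel metadata.
#' @export
setClass("TrialEpoch",
  representation(data = "matrix", sfreq = "numeric", t0Offset = "numeric",
                 stageMarks = "integer", stimulusId = "integer",
                 audio = "numeric", channelNames = "character",
                 channelKinds = "character"))

setValidity("TrialEpoch", function(object) {
  msg <- character()
  if (length(object@audio) && length(object@audio) != ncol(object@data))
    msg <- c(msg, "audio must be sample-aligned with the sensor data")
  if (length(object@channelNames) != nrow(object@data) ||
      length(object@channelKinds) != nrow(object@data))
    msg <- c(msg, "channel metadata must match the number of sensor rows")
  mk <- object@stageMarks[!is.na(object@stageMarks)]
  if (length(mk) > 1L && is.unsorted(mk))
    msg <- c(msg, "stageMarks must be ordered")
  if (length(msg)) msg else TRUE
})

#' Per-sample speech-segment labels
#'
#' The three-category partition of a production window around the acoustic
#' voice onset/offset, plus its binary collapse. Boundary convention: the
#' onset sample itself is the *last* `PRE` sample and the offset sample is the
#' *last* `SPEECH` sample (1-based, inclusive), i.e. `PRE` covers
#' `1..onset`, `SPEECH` covers `onset+1..offset` and `POST` covers
#' `offset+1..T`. The binary labels map `PRE` and `POST` to `NONSPEECH`.
#'
#' @slot labels3 factor of length T over `PRE`, `SPEECH`, `POST`.
#' @slot labels2 factor of length T over `SPEECH`, `NONSPEECH`.
#' @slot onset,offset integer boundary samples (see convention above).
#' @export
setClass("SegmentLabels",
  representation(labels3 = "factor", labels2 = "factor",
                 onset = "integer", offset = "integer"))

setValidity("SegmentLabels", function(object) {
  msg <- character()
  TT <- length(object@labels3)
  if (length(object@labels2) != TT)
    msg <- c(msg, "labels2 and labels3 must have equal length")
  if (!identical(levels(object@labels3), c("PRE", "SPEECH", "POST")))
    msg <- c(msg, "labels3 levels must be PRE, SPEECH, POST")
  if (!identical(levels(object@labels2), c("SPEECH", "NONSPEECH")))
    msg <- c(msg, "labels2 levels must be SPEECH, NONSPEECH")
  if (object@onset < 1L || object@onset >= object@offset || object@offset > TT)
    msg <- c(msg, "require 1 <= onset < offset <= T")
  if (length(msg)) msg else TRUE
})

#' Framewise feature sequence
#'
#' The T x 4 per-sample feature matrix extracted across sensors: `f1` sum of
#' absolute values, `f2` root mean square, `f3` cross-sensor standard
#' deviation (population convention), `f4` 1-based index of the
#' maximum-magnitude sensor.
#'
#' @slot features numeric T x 4 matrix with columns `f1..f4`.
#' @slot sfreq sampling rate of the feature rows.
#' @slot nSensors number of sensors the features were computed across
#'   (the range of `f4`).
#' @export
setClass("FeatureSequence",
  representation(features = "matrix", sfreq = "numeric",
                 nSensors = "integer"))

setValidity("FeatureSequence", function(object) {
  msg <- character()
  if (ncol(object@features) != 4L ||
      !identical(colnames(object@features), c("f1", "f2", "f3", "f4")))
    msg <- c(msg, "features must have the four columns f1, f2, f3, f4")
  f4 <- object@features[, 4L]
  if (length(f4) && (any(f4 < 1) || any(f4 > object@nSensors)))
    msg <- c(msg, "f4 must index sensors in 1..nSensors")
  if (length(msg)) msg else TRUE
})

#' Trained sequence-labeling model
#'
#' A trained recurrent voice-activity labeler: learned parameters, the
#' training configuration (see [lstmConfig]), input metadata needed to apply
#' it to new feature sequences, and the per-epoch training history used for
#' validation-based epoch selection. Serialize with [saveVadModel] /
#' [loadVadModel]; reloaded models predict bit-identically.
#'
#' @slot params list of layer parameter matrices.
#' @slot config the [lstmConfig] list used for training.
#' @slot nFeatures input dimensionality per time point.
#' @slot nSensors sensor count used to scale the sensor-index feature.
#' @slot standardize input standardization mode ("trial" or "none").
#' @slot history data.frame with per-epoch `loss`, `val_accuracy`.
#' @slot seed the integer seed the training run was initialized with.
#' @export
setClass("VadModel",
  representation(params = "list", config = "list", nFeatures = "integer",
                 nSensors = "integer", standardize = "character",
                 history = "data.frame", seed = "integer"))

#' Generator ground truth
#'
#' Per-trial ground truth emitted by [simulateSession]: acoustic onset/offset
#' (production-window milliseconds, boundary convention as in
#' [SegmentLabels]), artifact flags, and the set of speech-locked sensors.
#'
#' @slot trials data.frame with columns `trial`, `subject_id`, `stimulus_id`,
#'   `onset_ms`, `offset_ms`, `is_artifact`.
#' @slot speechSensors integer indices of the sensors that carry speech-locked
#'   amplitude elevation.
#' @export
setClass("GroundTruth",
  representation(trials = "data.frame", speechSensors = "integer"))

setValidity("GroundTruth", function(object) {
  tr <- object@trials
  need <- c("trial", "subject_id", "stimulus_id", "onset_ms", "offset_ms",
            "is_artifact")
  if (!all(need %in% names(tr)))
    return(paste("trials must have columns", paste(need, collapse = ", ")))
  if (any(tr$onset_ms >= tr$offset_ms))
    return("onset must precede offset in every trial")
  TRUE
})
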