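#' @rdname Recording-class
#' @param object,x an object.
#' @export
setGeneric("sensorData", function(x) standardGeneric("sensorData"))

#' @rdname Recording-class
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname Recording-class
#' @export
setGeneric("channelKinds", function(x) standardGeneric("channelKinds"))

#' @rdname Recording-class
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' @rdname Recording-class
#' @export
setGeneric("eventTable", function(x) standardGeneric("eventTable"))

#' @rdname TrialEpoch-class
#' @export
setGeneric("audioSignal", function(x) standardGeneric("audioSignal"))

#' @rdname TrialEpoch-class
#' @export
setGeneric("stageMarks", function(x) standardGeneric("stageMarks"))

#' @rdname TrialEpoch-class
#' @export
setGeneric("stimulusId", function(x) standardGeneric("stimulusId"))

#' @rdname SegmentLabels-class
#' @export
setGeneric("labels3", function(x) standardGeneric("labels3"))

#' @rdname SegmentLabels-class
#' @export
setGeneric("labels2", function(x) standardGeneric("labels2"))

#' @rdname SegmentLabels-class
#' @export
setGeneric("speechOnset", function(x) standardGeneric("speechOnset"))

#' @rdname SegmentLabels-class
#' @export
setGeneric("speechOffset", function(x) standardGeneric("speechOffset"))

#' @rdname FeatureSequence-class
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))

#' @rdname GroundTruth-class
#' @export
setGeneric("trialInfo", function(x) standardGeneric("trialInfo"))

#' @rdname GroundTruth-class
#' @export
setGeneric("speechSensors", function(x) standardGeneric("speechSensors"))

#' @rdname VadModel-class
#' @export
setGeneric("trainingHistory", function(x) standardGeneric("trainingHistory"))

setMethod("sensorData", "Recording", function(x) x@data)
setMethod("sensorData", "TrialEpoch", function(x) x@data)
setMethod("samplingRate", "Recording", function(x) x@sfreq)
setMethod("samplingRate", "TrialEpoch", function(x) x@sfreq)
setMethod("samplingRate", "FeatureSequence", function(x) x@sfreq)
setMethod("channelKinds", "Recording", function(x) x@channelKinds)
setMethod("channelKinds", "TrialEpoch", function(x) x@channelKinds)
setMethod("channelNames", "Recording", function(x) x@channelNames)
setMethod("channelNames", "TrialEpoch", function(x) x@channelNames)
setMethod("eventTable", "Recording", function(x) x@events)
setMethod("audioSignal", "TrialEpoch", function(x) x@audio)
setMethod("stageMarks", "TrialEpoch", function(x) x@stageMarks)
setMethod("stimulusId", "TrialEpoch", function(x) x@stimulusId)
setMethod("labels3", "SegmentLabels", function(x) x@labels3)
setMethod("labels2", "SegmentLabels", function(x) x@labels2)
setMethod("speechOnset", "SegmentLabels", function(x) x@onset)
setMethod("speechOffset", "SegmentLabels", function(x) x@offset)
setMethod("featureMatrix", "FeatureSequence", function(x) x@features)
setMethod("trialInfo", "GroundTruth", function(x) x@trials)
setMethod("speechSensors", "GroundTruth", function(x) x@speechSensors)
setMethod("trainingHistory", "VadModel", function(x) x@history)

#' @rdname Recording-class
#' @export
setMethod("dim", "Recording", function(x) dim(x@data))

#' @rdname TrialEpoch-class
#' @export
setMethod("dim", "TrialEpoch", function(x) dim(x@data))

setMethod("show", "Recording", function(object) {
  kinds <- table(object@channelKinds)
  cat(sprintf("Recording: %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(object@data), ncol(object@data), object@sfreq,
              ncol(object@data) / object@sfreq))
  cat("  channels:", paste(sprintf("%s=%d", names(kinds), kinds),
                           collapse = ", "), "\n")
  cat(sprintf("  events: %d\n", nrow(object@events)))
})

setMethod("show", "TrialEpoch", function(object) {
  cat(sprintf(
    "TrialEpoch: %d sensors x %d samples @ %g Hz, t0 = %+.2f s, stimulus %d\n",
    nrow(object@data), ncol(object@data), object@sfreq, object@t0Offset,
    object@stimulusId))
  mk <- object@stageMarks
  cat("  stage marks:", paste(sprintf("%s=%s", names(mk), mk),
                              collapse = ", "), "\n")
})

setMethod("show", "SegmentLabels", function(object) {
  cat(sprintf(
    "SegmentLabels: T = %d, Pre 1..%d | Speech %d..%d | Post %d..%d\n",
    length(object@labels3), object@onset, object@onset + 1L, object@offset,
    object@offset + 1L, length(object@labels3)))
})

setMethod("show", "FeatureSequence", function(object) {
  cat(sprintf("FeatureSequence: %d samples x 4 features @ %g Hz (%d sensors)\n",
              nrow(object@features), object@sfreq, object@nSensors))
})

setMethod("show", "VadModel", function(object) {
  cfg <- object@config
  cat(sprintf(
    "VadModel: %d-layer LSTM, %d hidden units, %d input features, seed %d\n",
    cfg$nLayers, cfg$hiddenUnits, object@nFeatures, object@seed))
  if (nrow(object@history))
    cat(sprintf("  trained %d epochs, best validation accuracy %.4f\n",
                nrow(object@history), max(object@history$val_accuracy)))
})

setMethod("show", "GroundTruth", function(object) {
  tr <- object@trials
  cat(sprintf("GroundTruth: %d trials (%d artifact), %d speech sensors\n",
              nrow(tr), sum(tr$is_artifact), length(object@speechSensors)))
})
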