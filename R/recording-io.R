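#' Construct a Recording
#'
#' @param data numeric matrix, channels x samples.
#' @param sfreq sampling rate in Hz.
#' @param channelNames optional character vector (defaults to `CH001...`).
#' @param channelKinds character vector of per-channel kinds; see
#'   [Recording-class].
#' @param events data.frame of stimulus events (`onset_sample`, `stimulus_id`,
#'   `subject_id`), or `NULL` for none.
#' @return a [Recording-class] object.
#' @export
Recording <- function(data, sfreq, channelNames = NULL,
                      channelKinds = rep("gradiometer", nrow(data)),
                      events = NULL) {
  data <- as.matrix(data)
  if (is.null(channelNames))
    channelNames <- sprintf("CH%03d", seq_len(nrow(data)))
  if (is.null(events))
    events <- data.frame(onset_sample = integer(), stimulus_id = integer(),
                         subject_id = character())
  new("Recording", data = data, sfreq = as.numeric(sfreq),
      channelNames = as.character(channelNames),
      channelKinds = as.character(channelKinds), events = events)
}

CONTAINER_FORMAT <- "megvad-recording"
CONTAINER_VERSION <- 1L

#' Write a recording to the native container
#'
#' Serializes the full session losslessly — data matrix, sampling rate,
#' channel metadata and event table — into a single file that
#' [readRecording] restores bit-identically.
#'
#' @param recording a [Recording-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeRecording <- function(recording, path) {
  stopifnot(is(recording, "Recording"))
  if (!all(is.finite(recording@data)))
    stop("non-finite data: recording contains NaN/Inf samples")
  payload <- list(format = CONTAINER_FORMAT, version = CONTAINER_VERSION,
                  data = recording@data, sfreq = recording@sfreq,
                  channel_names = recording@channelNames,
                  channel_kinds = recording@channelKinds,
                  events = recording@events)
  saveRDS(payload, path)
  invisible(path)
}

#' Read a recording
#'
#' Reads a session from the native container written by [writeRecording].
#' FIF import is not supported in this build; requesting it raises an
#' informative error.
#'
#' @param path file path.
#' @param format `"native"` (default) or `"fif"`.
#' @return a [Recording-class].
#' @export
readRecording <- function(path, format = c("native", "fif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "fif")
    stop("FIF import is not supported in this build; ",
         "convert to the native container first")
  payload <- readRDS(path)
  if (!is.list(payload) || !identical(payload$format, CONTAINER_FORMAT))
    stop("unknown format: not a native recording container")
  if (is.null(payload$sfreq)) stop("missing sampling rate")
  if (is.null(payload$data) || nrow(payload$data) == 0L)
    stop("empty channel set")
  Recording(payload$data, payload$sfreq, payload$channel_names,
            payload$channel_kinds, payload$events)
}

#' Read an event table from CSV
#'
#' Expects columns `onset_sample`, `stimulus_id`, `subject_id`.
#'
#' @param path CSV file path.
#' @return data.frame suitable for the `events` slot of a [Recording-class].
#' @export
readEventTable <- function(path) {
  ev <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("onset_sample", "stimulus_id", "subject_id")
  if (!all(need %in% names(ev)))
    stop("event table must have columns ", paste(need, collapse = ", "))
  ev$onset_sample <- as.integer(ev$onset_sample)
  ev$stimulus_id <- as.integer(ev$stimulus_id)
  ev
}

#' Protocol stage marks for an epoch
#'
#' Delayed overt-reading protocol: 0.5 s baseline, 1 s stimulus, 1 s
#' preparation, 2 s production. For an epoch whose first sample sits at
#' `t0Offset` seconds relative to stimulus onset, returns 1-based in-epoch
#' sample indices of the stimulus onset, preparation cue, production cue and
#' trial end (`NA` where a mark falls outside the epoch).
#' @noRd
protocolStageMarks <- function(sfreq, t0Offset, nSamples) {
  times <- c(stimulusOn = 0, prepCue = 1, productionCue = 2, trialEnd = 4)
  idx <- stats::setNames(as.integer(round((times - t0Offset) * sfreq)) + 1L,
                         names(times))
  idx[idx < 1L | idx > nSamples] <- NA_integer_
  idx
}

#' Cut a recording into trial epochs
#'
#' Epochs the session around each stimulus onset, from `window[1]` to
#' `window[2]` seconds relative to onset (default -0.5 s to 4.5 s, i.e.
#' `T = 5 * sfreq` samples). The acoustic channel is split off into the
#' `audio` slot of each epoch; all other channels form the sensor matrix.
#' Events whose window does not fit inside the recording are skipped with a
#' warning and reported in the `skipped` attribute.
#'
#' @param recording a [Recording-class] with an event table (or pass `events`).
#' @param events optional event data.frame overriding `eventTable(recording)`.
#' @param window numeric length-2, epoch window in seconds relative to
#'   stimulus onset.
#' @return list of [TrialEpoch-class]; attribute `skipped` holds the indices
#'   of out-of-bounds events.
#' @export
epochTrials <- function(recording, events = NULL, window = c(-0.5, 4.5)) {
  stopifnot(is(recording, "Recording"))
  if (is.null(events)) events <- recording@events
  if (nrow(events) == 0L) stop("no events to epoch")
  sf <- recording@sfreq
  nTotal <- ncol(recording@data)
  lenT <- as.integer(round((window[2] - window[1]) * sf))
  acoustic <- which(recording@channelKinds == "acoustic")
  sensorRows <- setdiff(seq_len(nrow(recording@data)), acoustic)

  epochs <- list()
  skipped <- integer()
  for (i in seq_len(nrow(events))) {
    start <- events$onset_sample[i] + as.integer(round(window[1] * sf))
    end <- start + lenT - 1L
    if (start < 1L || end > nTotal) {
      skipped <- c(skipped, i)
      next
    }
    idx <- start:end
    audio <- if (length(acoustic)) recording@data[acoustic[1L], idx]
             else numeric()
    epochs[[length(epochs) + 1L]] <- new("TrialEpoch",
      data = recording@data[sensorRows, idx, drop = FALSE], sfreq = sf,
      t0Offset = window[1],
      stageMarks = protocolStageMarks(sf, window[1], lenT),
      stimulusId = as.integer(events$stimulus_id[i]), audio = audio,
      channelNames = recording@channelNames[sensorRows],
      channelKinds = recording@channelKinds[sensorRows])
  }
  if (length(skipped))
    warning(length(skipped), " event(s) too close to the recording edge; ",
            "skipped: ", paste(skipped, collapse = ", "))
  attr(epochs, "skipped") <- skipped
  epochs
}
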