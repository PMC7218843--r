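# Channel selection, artifact-trial rejection, wavelet band restriction and
# production-window extraction.

#' Preprocessing configuration
#'
#' @param waveletName wavelet used for denoising (`"db4"`).
#' @param decompositionLevel wavelet decomposition depth; at a 1 kHz working
#'   rate, level 2 restricts the signal to the high-gamma band (< 125 Hz).
#' @param targetBandHz nominal upper edge of the retained band, used only to
#'   validate that `workingSfreq / 2^(decompositionLevel + 1)` does not exceed
#'   it.
#' @param artifactZscoreThreshold robust-z threshold for trial rejection.
#' @param workingSfreq analysis sampling rate; epochs at other rates are
#'   resampled (polyphase FIR) before denoising.
#' @param denoiseMode `"restrict"` (zero detail bands) or `"threshold"`
#'   (soft-threshold details); see [waveletBandRestrict].
#' @param flatThreshold across-trial variance below which a channel counts as
#'   unresponsive.
#' @param noiseThreshold multiple of the median channel variance above which
#'   a channel counts as noisy.
#' @return list of class `PreprocessConfig`.
#' @export
preprocessConfig <- function(waveletName = "db4", decompositionLevel = 2L,
                             targetBandHz = 125, artifactZscoreThreshold = 10,
                             workingSfreq = 1000,
                             denoiseMode = c("restrict", "threshold"),
                             flatThreshold = 1e-10, noiseThreshold = 25) {
  denoiseMode <- match.arg(denoiseMode)
  stopifnot(decompositionLevel >= 1L, workingSfreq > 0)
  approxBand <- workingSfreq / 2^(decompositionLevel + 1L)
  if (approxBand > targetBandHz)
    stop(sprintf(paste0("approximation band (%g Hz) exceeds the target band",
                        " (%g Hz); increase decompositionLevel"),
                 approxBand, targetBandHz))
  structure(list(waveletName = waveletName,
                 decompositionLevel = as.integer(decompositionLevel),
                 targetBandHz = targetBandHz,
                 artifactZscoreThreshold = artifactZscoreThreshold,
                 workingSfreq = workingSfreq, denoiseMode = denoiseMode,
                 flatThreshold = flatThreshold,
                 noiseThreshold = noiseThreshold),
            class = "PreprocessConfig")
}

#' Keep only gradiometer channels
#'
#' Planar gradiometers suppress distant noise sources and are the only sensor
#' kind analyzed. For a [TrialEpoch-class] the auxiliary acoustic signal
#' lives in its own slot and is untouched; for a [Recording-class] the
#' acoustic row is also retained (tagged as such) so labeling workflows
#' survive the selection.
#'
#' @param x a [Recording-class] or [TrialEpoch-class], or a list of epochs.
#' @return same type as `x`, restricted to gradiometer rows.
#' @export
selectGradiometers <- function(x) {
  if (is.list(x)) return(lapply(x, selectGradiometers))
  keep <- which(channelKinds(x) == "gradiometer")
  if (!length(keep)) stop("no gradiometer channels present")
  if (is(x, "Recording")) {
    keep <- sort(c(keep, which(x@channelKinds == "acoustic")))
    return(initialize(x, data = x@data[keep, , drop = FALSE],
                      channelNames = x@channelNames[keep],
                      channelKinds = x@channelKinds[keep]))
  }
  stopifnot(is(x, "TrialEpoch"))
  initialize(x, data = x@data[keep, , drop = FALSE],
             channelNames = x@channelNames[keep],
             channelKinds = x@channelKinds[keep])
}

#' Remove unresponsive or noisy channels
#'
#' A channel is *unresponsive* when its variance pooled across all trials is
#' below `flatThreshold`, and *noisy* when its variance exceeds
#' `noiseThreshold` times the median channel variance. Removal is applied
#' consistently to every trial; retained channels keep their order.
#'
#' @param epochs list of [TrialEpoch-class].
#' @param flatThreshold,noiseThreshold positive thresholds (defaults from
#'   [preprocessConfig]).
#' @return list with `epochs` (channels removed) and `dropped`
#'   (data.frame `channel`, `name`, `reason`).
#' @export
dropBadChannels <- function(epochs, flatThreshold = 1e-10,
                            noiseThreshold = 25) {
  stopifnot(length(epochs) >= 1L, flatThreshold > 0, noiseThreshold > 0)
  v <- rowMeans(vapply(epochs, function(e)
    apply(e@data, 1L, stats::var), numeric(nrow(epochs[[1L]]@data))))
  flat <- v < flatThreshold
  noisy <- !flat & v > noiseThreshold * stats::median(v)
  drop <- flat | noisy
  if (all(drop)) stop("channel removal would leave zero channels")
  dropped <- data.frame(channel = which(drop),
                        name = epochs[[1L]]@channelNames[drop],
                        reason = ifelse(flat[drop], "unresponsive", "noisy"))
  keep <- which(!drop)
  epochs <- lapply(epochs, function(e)
    initialize(e, data = e@data[keep, , drop = FALSE],
               channelNames = e@channelNames[keep],
               channelKinds = e@channelKinds[keep]))
  list(epochs = epochs, dropped = dropped)
}

#' Reject high-amplitude artifact trials
#'
#' Deterministic stand-in for visual artifact inspection: for every sensor
#' the per-trial peak absolute amplitudes form the session baseline
#' distribution; a trial is rejected when any sensor's peak exceeds the
#' median of that distribution by more than `zscoreThreshold` robust-z units
#' (MAD-scaled). Retained trials keep their order.
#'
#' @param epochs list of [TrialEpoch-class] (>= 1).
#' @param zscoreThreshold positive robust-z threshold (default 10).
#' @return list with `epochs` (kept), `rejected` (integer indices) and
#'   `report` (data.frame `trial`, `reason`).
#' @export
rejectArtifactTrials <- function(epochs, zscoreThreshold = 10) {
  stopifnot(length(epochs) >= 1L)
  if (zscoreThreshold <= 0) stop("zscoreThreshold must be positive")
  peaks <- vapply(epochs, function(e) apply(abs(e@data), 1L, max),
                  numeric(nrow(epochs[[1L]]@data)))  # sensors x trials
  med <- apply(peaks, 1L, stats::median)
  scale <- apply(peaks, 1L, stats::mad)
  if (all(scale <= 0)) scale[] <- 1
  else scale[scale <= 0] <- stats::median(scale[scale > 0])
  z <- (peaks - med) / scale
  bad <- apply(z > zscoreThreshold, 2L, any)
  if (all(bad))
    stop("all trials rejected; review the artifact z-score threshold")
  report <- data.frame(trial = which(bad),
                       reason = vapply(which(bad), function(i)
                         sprintf("peak robust-z %.1f on sensor %d",
                                 max(z[, i]), which.max(z[, i])),
                         character(1)))
  list(epochs = epochs[!bad], rejected = which(bad), report = report)
}

#' Resample a vector with zero phase
#'
#' Fourier-domain resampling: the spectrum is truncated (downsampling) or
#' zero-padded (upsampling) and inverse-transformed, so the operation is
#' exactly zero-phase — band-limited content is not delayed, which keeps the
#' millisecond labeling convention intact across acquisition rates.
#'
#' @param x numeric vector.
#' @param n2 target length.
#' @return numeric vector of length `n2`.
#' @export
resampleVector <- function(x, n2) {
  n <- length(x)
  if (n2 == n) return(x)
  X <- stats::fft(x)
  Y <- complex(n2)
  half <- min(n, n2) %/% 2L
  Y[seq_len(half + 1L)] <- X[seq_len(half + 1L)]
  if (half > 1L)
    Y[n2 - seq_len(half - 1L) + 1L] <- X[n - seq_len(half - 1L) + 1L]
  if (min(n, n2) %% 2L == 0L && n2 < n) {
    # split the Nyquist bin symmetrically when truncating
    Y[half + 1L] <- Re(X[half + 1L])
  }
  Re(stats::fft(Y, inverse = TRUE)) * (n2 / n) / n2
}

#' Resample an epoch to a target rate
#'
#' Zero-phase Fourier resampling ([resampleVector]) of every sensor row and
#' the audio channel, with stage marks rescaled.
#'
#' @param epoch a [TrialEpoch-class].
#' @param targetSfreq target sampling rate (Hz).
#' @return resampled [TrialEpoch-class].
#' @export
resampleEpoch <- function(epoch, targetSfreq) {
  if (epoch@sfreq == targetSfreq) return(epoch)
  r <- targetSfreq / epoch@sfreq
  n2 <- as.integer(round(ncol(epoch@data) * r))
  data <- t(apply(epoch@data, 1L, resampleVector, n2 = n2))
  audio <- if (length(epoch@audio)) resampleVector(epoch@audio, n2)
           else numeric()
  marks <- stats::setNames(as.integer(round((epoch@stageMarks - 1L) * r)) + 1L,
                           names(epoch@stageMarks))
  marks[marks > n2] <- NA_integer_
  initialize(epoch, data = data, sfreq = targetSfreq, audio = audio,
             stageMarks = marks)
}

#' Wavelet-denoise an epoch
#'
#' Per channel: decompose with `config$waveletName` to
#' `config$decompositionLevel`, discard the detail bands and reconstruct from
#' the approximation ([waveletBandRestrict]), restricting content to the
#' high-gamma band. Epochs not at `config$workingSfreq` are resampled first.
#' The audio channel is left untouched.
#'
#' @param epoch a [TrialEpoch-class].
#' @param config a [preprocessConfig].
#' @return denoised [TrialEpoch-class] at the working rate.
#' @export
waveletDenoise <- function(epoch, config = preprocessConfig()) {
  stopifnot(is(epoch, "TrialEpoch"))
  epoch <- resampleEpoch(epoch, config$workingSfreq)
  den <- t(apply(epoch@data, 1L, waveletBandRestrict,
                 level = config$decompositionLevel,
                 wavelet = config$waveletName, mode = config$denoiseMode))
  initialize(epoch, data = den)
}

#' Extract the production window
#'
#' Restricts an epoch to the 2 s analysis period starting at the speech
#' production cue: at 1 kHz, window sample `m` is millisecond `m` after the
#' cue. The audio channel is cut identically.
#'
#' @param epoch a [TrialEpoch-class] with a `productionCue` stage mark.
#' @return [TrialEpoch-class] with `2 * sfreq` samples, `t0Offset = 2`.
#' @export
extractProductionWindow <- function(epoch) {
  stopifnot(is(epoch, "TrialEpoch"))
  cue <- epoch@stageMarks[["productionCue"]]
  if (is.na(cue)) stop("missing stage marks: no production cue in epoch")
  len <- as.integer(round(2 * epoch@sfreq))
  if (cue + len - 1L > ncol(epoch@data))
    stop("epoch too short for a full production window")
  idx <- cue:(cue + len - 1L)
  initialize(epoch, data = epoch@data[, idx, drop = FALSE],
             audio = if (length(epoch@audio)) epoch@audio[idx] else numeric(),
             t0Offset = 2,
             stageMarks = protocolStageMarks(epoch@sfreq, 2, len))
}
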