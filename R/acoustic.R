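# Acoustic ground-truth labeling: Wiener denoising of the microphone
# channel, energy-based voice onset/offset detection, and the per-sample
# Pre/Speech/Post label partition.

#' Voice-activity detector configuration
#'
#' Framed-energy detection against a noise floor estimated from the initial
#' silence, with gap bridging so intra-phrase pauses are not split (pauses
#' within a phrase are not meant to be predicted), plus a short-frame
#' boundary refinement. All constants are in milliseconds of the production
#' window.
#'
#' @param frameMs analysis frame length.
#' @param hopMs hop between frame starts.
#' @param thresholdFactor a frame is speech when its energy exceeds
#'   `thresholdFactor` times the noise floor (median energy over the first
#'   `noiseFloorMs`).
#' @param minSpeechMs minimum span for a detected utterance.
#' @param minSilenceGapMs sub-threshold gaps shorter than this are bridged.
#' @param noiseFloorMs initial window used for the noise-floor estimate.
#' @param minRunMs supra-threshold runs shorter than this are discarded
#'   *before* gap bridging: a single loud noise sample lights up a full
#'   frame-length of overlapping frames, and bridging would otherwise absorb
#'   such glitches into the speech span.
#' @param refineWindowMs half-width of the window around each coarse
#'   boundary in which the sample-level variance-changepoint refinement is
#'   performed.
#' @param refineSmoothMs width of the centered moving average applied to the
#'   squared samples before the changepoint fit; damps the chi-squared
#'   variance of single squared samples.
#' @param refinePenalty asymmetric penalty (nats per sample) pulling the
#'   changepoint toward the quiet side: misassigning quiet samples as speech
#'   is far cheaper in likelihood than the reverse, so a small penalty
#'   equalizes the two error tails.
#' @return list of class `VadDetectorConfig`.
#' @export
vadDetectorConfig <- function(frameMs = 10, hopMs = 1, thresholdFactor = 3,
                              minSpeechMs = 100, minSilenceGapMs = 250,
                              noiseFloorMs = 200, minRunMs = 30,
                              refineWindowMs = 100, refineSmoothMs = 7,
                              refinePenalty = 0.4) {
  stopifnot(frameMs >= hopMs, thresholdFactor > 0, minSpeechMs > 0,
            minSilenceGapMs >= 0, refineWindowMs >= 2, minRunMs >= frameMs,
            refineSmoothMs >= 1, refinePenalty >= 0)
  structure(list(frameMs = frameMs, hopMs = hopMs,
                 thresholdFactor = thresholdFactor, minSpeechMs = minSpeechMs,
                 minSilenceGapMs = minSilenceGapMs,
                 noiseFloorMs = noiseFloorMs, minRunMs = minRunMs,
                 refineWindowMs = refineWindowMs,
                 refineSmoothMs = refineSmoothMs,
                 refinePenalty = refinePenalty),
            class = "VadDetectorConfig")
}

# frame energies (mean square) for frames of length fl starting every hop
# samples; returns vector indexed by frame start sample
frameEnergy <- function(x, fl, hop = 1L) {
  cs <- c(0, cumsum(x^2))
  starts <- seq(1L, length(x) - fl + 1L, by = hop)
  (cs[starts + fl] - cs[starts]) / fl
}

runsOf <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], end = ends[r$values])
}

#' Wiener-denoise an audio signal
#'
#' Single-pass spectral-gain Wiener filter: the noise power spectrum is
#' estimated from the trial's initial silence (`noiseWindow`), and each
#' short-time frame is attenuated per frequency bin by the Wiener gain
#' `max(1 - Pn/Pxx, 0)`, optionally smoothed across frames, then
#' overlap-added back. Signals that are already clean pass through nearly
#' unchanged; an all-zero input returns all zeros.
#'
#' @param audio numeric vector.
#' @param sfreq sampling rate (Hz).
#' @param noiseWindow length-2 sample range of the noise profile (default the
#'   first 200 ms).
#' @param frameMs STFT frame length (Hann window, 50% overlap).
#' @param smoothing exponential smoothing constant in `[0, 1)` applied to the
#'   per-frame power-spectrum estimate before the gain is computed (0 =
#'   none). Smoothing the PSD rather than the gain damps the chi-squared
#'   variance of single periodograms — the source of musical-noise
#'   distortion. The default is 0 because the smoothed PSD lingers across
#'   frame boundaries, which blurs the sharp energy edges that onset/offset
#'   detection relies on; enable it when denoising quality matters more than
#'   boundary sharpness.
#' @param gainFloor minimum spectral gain: silence is attenuated by this
#'   factor rather than annihilated, so downstream energy statistics (noise
#'   floors, thresholds) keep their proportions.
#' @return denoised numeric vector, same length as `audio`.
#' @export
wienerDenoiseAudio <- function(audio, sfreq,
                               noiseWindow = c(1L, round(0.2 * sfreq)),
                               frameMs = 32, smoothing = 0,
                               gainFloor = 0.15) {
  n <- length(audio)
  if (n == 0L) stop("audio is empty")
  if (noiseWindow[2L] > n) stop("noise window longer than audio")
  if (all(audio == 0)) return(audio)
  fl <- max(8L, as.integer(round(frameMs * sfreq / 1000)))
  fl <- fl + fl %% 2L
  hop <- fl %/% 2L
  win <- 0.5 * (1 - cos(2 * pi * (seq_len(fl) - 1) / fl))  # periodic Hann

  pad <- c(audio, numeric(fl))
  starts <- seq(1L, n, by = hop)
  # noise PSD: averaged periodogram over frames inside the noise window
  nStarts <- starts[starts + fl - 1L <= noiseWindow[2L]]
  if (!length(nStarts)) nStarts <- starts[1L]
  Pn <- rowMeans(vapply(nStarts, function(s)
    Mod(stats::fft(pad[s:(s + fl - 1L)] * win))^2, numeric(fl)))

  out <- numeric(n + fl)
  norm <- numeric(n + fl)
  Psm <- NULL
  for (s in starts) {
    fr <- pad[s:(s + fl - 1L)] * win
    Fx <- stats::fft(fr)
    Pxx <- Mod(Fx)^2
    Psm <- if (smoothing > 0 && !is.null(Psm))
      smoothing * Psm + (1 - smoothing) * Pxx else Pxx
    g <- ifelse(Psm > 0, pmax(1 - Pn / Psm, gainFloor), gainFloor)
    rec <- Re(stats::fft(Fx * g, inverse = TRUE)) / fl
    idx <- s:(s + fl - 1L)
    out[idx] <- out[idx] + rec * win
    norm[idx] <- norm[idx] + win^2
  }
  out <- out[seq_len(n)] / pmax(norm[seq_len(n)], 1e-12)
  out
}

#' Detect voice onset and offset in an acoustic signal
#'
#' Short-time energy per frame; the noise floor is the median energy over the
#' initial silence; frames exceeding `thresholdFactor` times the floor are
#' speech; sub-threshold gaps shorter than `minSilenceGapMs` are bridged and
#' runs shorter than `minSpeechMs` discarded. Each boundary of the longest
#' surviving run is then refined to sample resolution by a two-segment
#' Gaussian variance-changepoint fit (maximum-likelihood split of the sample
#' energies) in a window around the coarse boundary. The returned convention
#' matches
#' the labeling rule: `onset` is the last sample *before* voicing (itself
#' labeled Pre-Speech) and `offset` the last voiced sample.
#'
#' @param audio numeric vector (one production window).
#' @param sfreq sampling rate (Hz).
#' @param config a [vadDetectorConfig].
#' @return list with `detected` (logical), `onset`, `offset` (1-based
#'   samples; `NA` when no voice was detected — the trial should be flagged
#'   like an untimely articulation).
#' @export
detectVoiceActivity <- function(audio, sfreq, config = vadDetectorConfig()) {
  stopifnot(inherits(config, "VadDetectorConfig"))
  ms <- function(v) max(1L, as.integer(round(v * sfreq / 1000)))
  fl <- ms(config$frameMs)
  hop <- ms(config$hopMs)
  TT <- length(audio)
  if (TT < fl + 1L) stop("audio shorter than one analysis frame")

  e <- frameEnergy(audio, fl, hop)
  starts <- seq(1L, TT - fl + 1L, by = hop)
  nFloor <- stats::median(e[starts + fl - 1L <= ms(config$noiseFloorMs)])
  if (!is.finite(nFloor) || nFloor <= 0)
    nFloor <- max(max(e) * 1e-10, .Machine$double.xmin)
  mask <- e > config$thresholdFactor * nFloor
  none <- list(detected = FALSE, onset = NA_integer_, offset = NA_integer_)
  if (!any(mask)) return(none)

  runs <- runsOf(mask)
  # glitch filter: drop runs shorter than minRunMs before bridging
  span <- (runs$end - runs$start) * hop + fl
  runs <- runs[span >= ms(config$minRunMs), , drop = FALSE]
  if (!nrow(runs)) return(none)
  # bridge sub-threshold gaps shorter than the intra-phrase pause limit
  if (nrow(runs) > 1L) {
    gapLimit <- ms(config$minSilenceGapMs) / hop
    keepRow <- rep(TRUE, nrow(runs))
    for (i in seq_len(nrow(runs) - 1L))
      if (runs$start[i + 1L] - runs$end[i] - 1L < gapLimit) {
        runs$start[i + 1L] <- runs$start[i]
        keepRow[i] <- FALSE
      }
    runs <- runs[keepRow, , drop = FALSE]
  }
  spanMs <- (runs$end - runs$start) * hop + fl
  runs <- runs[spanMs >= ms(config$minSpeechMs), , drop = FALSE]
  if (!nrow(runs)) return(none)
  best <- which.max(runs$end - runs$start)
  cFirst <- starts[runs$start[best]]           # first supra-threshold frame
  cLast <- starts[runs$end[best]] + fl - 1L    # last covered sample

  # sample-level boundary refinement: variance-changepoint fit of the
  # (smoothed) squared samples in a window around each coarse boundary.
  # The quiet-side variance is anchored at the noise floor (estimated from
  # 200 ms of silence, far more precise than the local window); the loud
  # side is the right-segment empirical level floored at thresholdFactor
  # times the noise floor; an asymmetric penalty equalizes the error tails.
  w <- ms(config$refineWindowMs)
  # smoothing trades edge sharpness for variance: only worthwhile in the
  # low-SNR regime; at high SNR the unsmoothed fit is already exact and
  # smoothing would blur the boundary by half the smoothing window
  speechLevel <- stats::median(e[runs$start[best]:runs$end[best]])
  sm <- if (speechLevel > 50 * nFloor) 1L else ms(config$refineSmoothMs)
  pen <- config$refinePenalty
  changepoint <- function(a, b, quietLeft = TRUE) {
    a <- max(1L, a); b <- min(TT, b)
    if (b - a < 4L) return(NA_integer_)
    sq <- audio[a:b]^2
    n0 <- length(sq)
    if (!quietLeft) sq <- rev(sq)
    if (sm > 1L) {
      sq <- as.numeric(stats::filter(sq, rep(1 / sm, sm), sides = 2))
      drop0 <- which(!is.na(sq))[1L] - 1L
      sq <- sq[!is.na(sq)]
    } else drop0 <- 0L
    n <- length(sq)
    cs <- cumsum(sq)
    tot <- cs[n]
    k <- seq_len(n - 1L)
    v2 <- pmax((tot - cs[k]) / (n - k), config$thresholdFactor * nFloor)
    ll <- -(cs[k] / nFloor + k * log(nFloor)) -
      ((tot - cs[k]) / v2 + (n - k) * log(v2)) + pen * k
    kk <- drop0 + k[which.max(ll)]
    if (!quietLeft) kk <- n0 - kk
    a + kk - 1L
  }
  # onset = last quiet sample before the energy step up
  cpOn <- changepoint(cFirst - w, cFirst + fl + w, quietLeft = TRUE)
  onset <- if (is.na(cpOn)) cFirst - 1L else cpOn
  # offset = last loud sample before the step down (quiet on the right)
  cpOff <- changepoint(cLast - fl - w, cLast + w, quietLeft = FALSE)
  offset <- if (is.na(cpOff)) cLast else cpOff
  onset <- max(1L, as.integer(onset))
  offset <- min(TT, as.integer(offset))
  if (onset >= offset) return(none)
  list(detected = TRUE, onset = onset, offset = offset)
}

#' Per-sample Pre/Speech/Post labels from onset and offset
#'
#' The exact three-way partition of a `T`-sample production window: samples
#' `1..onset` are `PRE` (the onset sample — the last millisecond before
#' voicing — is itself Pre-Speech), `onset+1..offset` are `SPEECH`, and
#' `offset+1..T` are `POST` (empty when `offset == T`; documented edge case).
#' The binary labels collapse `PRE` and `POST` into `NONSPEECH`.
#'
#' @param onset,offset 1-based boundary samples, `1 <= onset < offset <= T`.
#' @param T window length in samples.
#' @return a [SegmentLabels-class].
#' @export
labelSegments <- function(onset, offset, T) {
  onset <- as.integer(onset); offset <- as.integer(offset); T <- as.integer(T)
  if (onset < 1L || onset >= offset) stop("require 1 <= onset < offset")
  if (offset > T) stop("offset exceeds the window length")
  l3 <- factor(rep(c("PRE", "SPEECH", "POST"),
                   c(onset, offset - onset, T - offset)),
               levels = c("PRE", "SPEECH", "POST"))
  l2 <- collapseLabels(l3)
  new("SegmentLabels", labels3 = l3, labels2 = l2,
      onset = onset, offset = offset)
}

#' Collapse three-way labels to binary
#'
#' Pure function of the three-way labels: `PRE` and `POST` map to
#' `NONSPEECH`, `SPEECH` stays.
#'
#' @param l3 factor over `PRE`, `SPEECH`, `POST` (or a
#'   [SegmentLabels-class]).
#' @return factor over `SPEECH`, `NONSPEECH`.
#' @export
collapseLabels <- function(l3) {
  if (is(l3, "SegmentLabels")) l3 <- l3@labels3
  factor(ifelse(l3 == "SPEECH", "SPEECH", "NONSPEECH"),
         levels = c("SPEECH", "NONSPEECH"))
}
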