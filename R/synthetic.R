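# Synthetic delayed overt-reading sessions with known ground truth.
#
# Per trial: 0.5 s baseline, 1 s stimulus, 1 s preparation, 2 s production.
# A designated subset of sensors carries elevated-amplitude activity
# time-locked (with a small neural lead) to a synthetic acoustic burst on the
# microphone channel. Biophysical realism (dipole forward modelling,
# inter-sensor covariance of real MEG) is deliberately not attempted: the
# downstream pipeline consumes only sensor amplitude statistics.

#' Run an expression under a temporary RNG seed
#' @noRd
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  force(expr)
}

#' Simulation configuration
#'
#' Defaults reproduce the study conditions of the delayed overt-reading
#' protocol: 5 phrase stimuli x 100 trials each, 1 kHz working rate (one
#' sample = one millisecond), ~15% of sensors speech-locked, acoustic onset
#' 300-600 ms after the production cue, speech duration 400-900 ms, neural
#' activity leading the acoustic onset by 10 ms, and a 25% artifact-trial
#' rate.
#'
#' @param nSensors number of neuromagnetic sensor channels.
#' @param sfreq sampling rate (Hz).
#' @param nTrialsPerStimulus trials per stimulus.
#' @param nStimuli number of phrase stimuli.
#' @param speechSensorFraction fraction of sensors carrying speech-locked
#'   amplitude elevation.
#' @param snrDb amplitude elevation (dB) of speech sensors during speech
#'   relative to baseline; 0 means no decodable neural signal.
#' @param onsetJitterMs length-2 range (uniform) of acoustic onset latency
#'   after the production cue, in ms (boundary convention: the drawn value is
#'   the last pre-speech millisecond).
#' @param speechDurationMs length-2 range (uniform) of speech duration in ms.
#' @param neuralLeadMs milliseconds by which neural activation precedes the
#'   acoustic onset.
#' @param artifactTrialRate probability that a trial carries a high-amplitude
#'   artifact transient.
#' @param audioSnrDb acoustic burst-over-background SNR on the microphone
#'   channel, in dB.
#' @param sharedBackgroundWeight weight of a low-rank background term shared
#'   across sensors (0 = independent sensor noise).
#' @param subjectId subject identifier written into the event table.
#' @param seed integer RNG seed; the whole session is deterministic given it.
#' @return a validated list of class `SimulationConfig`.
#' @export
simConfig <- function(nSensors = 200L, sfreq = 1000, nTrialsPerStimulus = 100L,
                      nStimuli = 5L, speechSensorFraction = 0.15, snrDb = 10,
                      onsetJitterMs = c(300, 600),
                      speechDurationMs = c(400, 900), neuralLeadMs = 10,
                      artifactTrialRate = 0.25, audioSnrDb = 10,
                      sharedBackgroundWeight = 0.3, subjectId = "S01",
                      seed = 1L) {
  cfg <- list(nSensors = as.integer(nSensors), sfreq = sfreq,
              nTrialsPerStimulus = as.integer(nTrialsPerStimulus),
              nStimuli = as.integer(nStimuli),
              speechSensorFraction = speechSensorFraction, snrDb = snrDb,
              onsetJitterMs = onsetJitterMs,
              speechDurationMs = speechDurationMs,
              neuralLeadMs = neuralLeadMs,
              artifactTrialRate = artifactTrialRate, audioSnrDb = audioSnrDb,
              sharedBackgroundWeight = sharedBackgroundWeight,
              subjectId = subjectId, seed = as.integer(seed))
  stopifnot(cfg$speechSensorFraction > 0, cfg$speechSensorFraction <= 1,
            cfg$neuralLeadMs >= 0, cfg$sfreq > 0,
            cfg$artifactTrialRate >= 0, cfg$artifactTrialRate <= 1)
  if (max(onsetJitterMs) + max(speechDurationMs) > 2000)
    stop("onset jitter plus speech duration must fit the 2 s production stage")
  class(cfg) <- "SimulationConfig"
  cfg
}

#' 1/f-shaped band-limited noise (unit variance)
#'
#' Spectrally shaped Gaussian noise: amplitude ~ 1/sqrt(f) with a steep
#' roll-off above `cutHz`, so the content below the high-gamma band dominates.
#' @noRd
colouredNoise <- function(n, sfreq, cutHz = 125) {
  m <- stats::nextn(n, 2)  # power-of-two FFT length, truncated afterwards
  z <- stats::fft(stats::rnorm(m))
  k <- 0:(m - 1)
  f <- pmin(k, m - k) * sfreq / m
  shape <- 1 / sqrt(pmax(f, 2)) / sqrt(1 + (f / cutHz)^16)
  x <- Re(stats::fft(z * shape, inverse = TRUE))[seq_len(n)] / m
  x / stats::sd(x)
}

# in-trial ramped gain envelope: 1 outside [from, to], `gain` inside, with
# `rampMs`-long cosine ramps kept inside the interval
rampedEnvelope <- function(n, from, to, gain, rampMs = 5L) {
  env <- rep(1, n)
  len <- to - from + 1L
  ramp <- min(rampMs, floor(len / 2))
  w <- rep(1, len)
  if (ramp > 0) {
    up <- 0.5 * (1 - cos(pi * seq_len(ramp) / (ramp + 1)))
    w[seq_len(ramp)] <- up
    w[len + 1L - seq_len(ramp)] <- up
  }
  env[from:to] <- 1 + (gain - 1) * w
  env
}

#' Simulate a speech-task session
#'
#' Generates one subject's continuous multichannel session following the
#' time-locked delayed overt-reading protocol, together with its event table
#' and the ground truth every downstream stage is tested against. Sensor
#' channels are 1/f-shaped band-limited noise; during
#' `[acoustic onset - neuralLeadMs, acoustic offset]` the designated speech
#' sensors are amplitude-scaled by `10^(snrDb/20)`; the microphone channel
#' carries an amplitude-modulated noise burst exactly over the speech span
#' plus background noise; artifact trials receive high-amplitude transients.
#' Fully deterministic given `config$seed`.
#'
#' @param config a [simConfig] list.
#' @return list with elements `recording` ([Recording-class], acoustic channel
#'   last, events embedded), `events` (data.frame) and `truth`
#'   ([GroundTruth-class], onset/offset in production-window ms, paper
#'   convention: onset = last pre-speech ms).
#' @export
simulateSession <- function(config = simConfig()) {
  stopifnot(inherits(config, "SimulationConfig"))
  withSeed(config$seed, {
    sf <- config$sfreq
    nTrials <- config$nTrialsPerStimulus * config$nStimuli
    spacing <- as.integer(round(5.5 * sf))
    preRoll <- as.integer(round(1.0 * sf))
    nTotal <- preRoll + nTrials * spacing + as.integer(round(0.5 * sf))
    S <- config$nSensors

    stimulusOrder <- sample(rep(seq_len(config$nStimuli),
                                config$nTrialsPerStimulus))
    onsets <- preRoll + (seq_len(nTrials) - 1L) * spacing + 1L
    events <- data.frame(onset_sample = onsets, stimulus_id = stimulusOrder,
                         subject_id = config$subjectId)

    nSpeech <- max(1L, round(config$speechSensorFraction * S))
    speechSensors <- sort(sample.int(S, nSpeech))
    isArtifact <- stats::runif(nTrials) < config$artifactTrialRate
    onsetMs <- round(stats::runif(nTrials, config$onsetJitterMs[1],
                                  config$onsetJitterMs[2]))
    durMs <- round(stats::runif(nTrials, config$speechDurationMs[1],
                                config$speechDurationMs[2]))
    offsetMs <- onsetMs + durMs

    gain <- 10^(config$snrDb / 20)
    w <- config$sharedBackgroundWeight
    nShared <- 2L
    shared <- vapply(seq_len(nShared), function(i) colouredNoise(nTotal, sf),
                     numeric(nTotal))
    loadings <- matrix(stats::rnorm(S * nShared) / sqrt(nShared), S, nShared)

    data <- matrix(0, S + 1L, nTotal)
    # absolute sample index of production-window millisecond m for trial i:
    # epoch start = onset - 0.5*sf, production cue at epoch sample 2.5*sf + 1
    prodAbs <- function(i, m) onsets[i] + as.integer(round(2 * sf)) + m - 1L

    for (s in seq_len(S)) {
      x <- sqrt(1 - w^2) * colouredNoise(nTotal, sf) +
        w * as.numeric(loadings[s, ] %*% t(shared))
      if (s %in% speechSensors && gain != 1) {
        for (i in seq_len(nTrials)) {
          from <- prodAbs(i, onsetMs[i] + 1L -
                            as.integer(round(config$neuralLeadMs)))
          to <- prodAbs(i, offsetMs[i])
          env <- rampedEnvelope(to - from + 1L, 1L, to - from + 1L, gain,
                                rampMs = as.integer(round(0.005 * sf)))
          x[from:to] <- x[from:to] * env
        }
      }
      data[s, ] <- x
    }

    # artifact transients: 50 ms high-amplitude bursts on a random subset of
    # sensors, anywhere inside the trial window (>= 10x baseline std by
    # construction; 25x used)
    artLen <- as.integer(round(0.05 * sf))
    for (i in which(isArtifact)) {
      hit <- sample.int(S, max(2L, round(0.3 * S)))
      at <- onsets[i] + sample.int(as.integer(4 * sf) - artLen, 1L)
      shape <- 25 * sin(pi * seq_len(artLen) / artLen)^2
      data[hit, at:(at + artLen - 1L)] <-
        data[hit, at:(at + artLen - 1L)] +
        matrix(shape, length(hit), artLen, byrow = TRUE) *
          sign(stats::rnorm(length(hit)))
    }

    # acoustic channel: background noise + amplitude-modulated burst over
    # the exact speech span; the modulator is normalized to unit mean power
    # so the burst sits exactly audioSnrDb above the background
    burstGain <- 10^(config$audioSnrDb / 20)
    audio <- stats::rnorm(nTotal) * 0.05
    modDepth <- 0.1
    modNorm <- sqrt(1 + modDepth^2 / 2)
    for (i in seq_len(nTrials)) {
      from <- prodAbs(i, onsetMs[i] + 1L)
      to <- prodAbs(i, offsetMs[i])
      len <- to - from + 1L
      mod <- (1 + modDepth * sin(2 * pi * 6 * seq_len(len) / sf +
                                 stats::runif(1, 0, 2 * pi))) / modNorm
      audio[from:to] <- 0.05 * burstGain * stats::rnorm(len) * mod
    }
    data[S + 1L, ] <- audio

    rec <- Recording(data, sf,
                     channelNames = c(sprintf("MEG%03d", seq_len(S)), "MIC"),
                     channelKinds = c(rep("gradiometer", S), "acoustic"),
                     events = events)
    truth <- new("GroundTruth",
                 trials = data.frame(trial = seq_len(nTrials),
                                     subject_id = config$subjectId,
                                     stimulus_id = stimulusOrder,
                                     onset_ms = as.integer(onsetMs),
                                     offset_ms = as.integer(offsetMs),
                                     is_artifact = isArtifact),
                 speechSensors = as.integer(speechSensors))
    list(recording = rec, events = events, truth = truth)
  })
}

#' Worked labeling example
#'
#' A single 2000 ms production-window trial whose acoustic burst spans
#' exactly milliseconds 402-931 (1-based, inclusive): the subject "starts
#' speaking" at 401 ms after the cue and ends at 931 ms, the boundary
#' convention all labeling code must preserve. Sensors include three
#' speech-locked channels at 20 dB elevation; the audio burst sits 40 dB
#' above the background. Deterministic.
#'
#' @param sfreq sampling rate; at the default 1000 Hz one sample is one ms.
#' @return list with `epoch` ([TrialEpoch-class] restricted to the production
#'   window) and `truth` ([GroundTruth-class] with onset 401, offset 931).
#' @export
makeWorkedExample <- function(sfreq = 1000) {
  withSeed(20200416L, {
    TT <- as.integer(round(2 * sfreq))
    S <- 20L
    speech <- c(3L, 8L, 15L)
    onMs <- as.integer(round(401 * sfreq / 1000))
    offMs <- as.integer(round(931 * sfreq / 1000))
    lead <- as.integer(round(10 * sfreq / 1000))
    data <- matrix(0, S, TT)
    for (s in seq_len(S)) {
      x <- colouredNoise(TT, sfreq)
      if (s %in% speech)
        x <- x * rampedEnvelope(TT, onMs + 1L - lead, offMs, 10,
                                rampMs = as.integer(round(0.005 * sfreq)))
      data[s, ] <- x
    }
    audio <- 0.005 * stats::rnorm(TT)
    len <- offMs - onMs
    audio[(onMs + 1L):offMs] <- 0.5 * stats::rnorm(len) *
      (1 + 0.1 * sin(2 * pi * 6 * seq_len(len) / sfreq)) / sqrt(1.005)
    epoch <- new("TrialEpoch", data = data, sfreq = sfreq, t0Offset = 2.0,
                 stageMarks = protocolStageMarks(sfreq, 2.0, TT),
                 stimulusId = 2L, audio = audio,
                 channelNames = sprintf("MEG%03d", seq_len(S)),
                 channelKinds = rep("gradiometer", S))
    truth <- new("GroundTruth",
                 trials = data.frame(trial = 1L, subject_id = "EXAMPLE",
                                     stimulus_id = 2L, onset_ms = 401L,
                                     offset_ms = 931L, is_artifact = FALSE),
                 speechSensors = speech)
    list(epoch = epoch, truth = truth)
  })
}
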