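mkEpoch <- function(data, sfreq = 1000, audio = numeric(),
                    kinds = rep("gradiometer", nrow(data))) {
  new("TrialEpoch", data = data, sfreq = sfreq, t0Offset = -0.5,
      stageMarks = megvad:::protocolStageMarks(sfreq, -0.5, ncol(data)),
      stimulusId = 1L, audio = audio,
      channelNames = sprintf("CH%02d", seq_len(nrow(data))),
      channelKinds = kinds)
}

test_that("gradiometer selection keeps exactly the gradiometer rows", {
  set.seed(1)
  e <- mkEpoch(matrix(rnorm(4 * 100), 4),
               kinds = c("gradiometer", "magnetometer", "gradiometer", "eog"))
  g <- selectGradiometers(e)
  expect_identical(nrow(sensorData(g)), 2L)
  expect_true(all(channelKinds(g) == "gradiometer"))
  expect_identical(sensorData(g), sensorData(e)[c(1L, 3L), ])
  # all-gradiometer input is the identity
  allg <- mkEpoch(matrix(rnorm(300), 3))
  expect_identical(sensorData(selectGradiometers(allg)), sensorData(allg))
  expect_error(selectGradiometers(
    mkEpoch(matrix(0, 2, 10), kinds = c("eog", "ecg"))), "no gradiometer")
  # on a Recording the acoustic row survives for labeling
  sess <- tinySession()
  sel <- selectGradiometers(sess$recording)
  expect_identical(sum(channelKinds(sel) == "acoustic"), 1L)
})

test_that("flat and noisy channels are dropped consistently", {
  set.seed(2)
  epochs <- lapply(1:4, function(i) {
    d <- matrix(rnorm(5 * 200), 5)
    d[2L, ] <- 0                 # unresponsive
    d[4L, ] <- rnorm(200, sd = 10)  # 100x variance
    mkEpoch(d)
  })
  res <- dropBadChannels(epochs, flatThreshold = 1e-10, noiseThreshold = 25)
  expect_identical(res$dropped$channel, c(2L, 4L))
  expect_identical(res$dropped$reason, c("unresponsive", "noisy"))
  expect_identical(nrow(sensorData(res$epochs[[1L]])), 3L)
  # retained channels keep their order
  expect_identical(channelNames(res$epochs[[1L]]), c("CH01", "CH03", "CH05"))
  expect_error(dropBadChannels(lapply(1:2, function(i) mkEpoch(matrix(0, 2, 50)))),
               "zero channels")
})

test_that("a clean simulated session loses no channels", {
  epochs <- epochTrials(tinySession()$recording)
  res <- dropBadChannels(selectGradiometers(epochs))
  expect_identical(nrow(res$dropped), 0L)
})

test_that("artifact rejection recovers the generator's artifact flags", {
  sess <- simulateSession(simConfig(nSensors = 4L, nTrialsPerStimulus = 100L,
                                    nStimuli = 3L, seed = 61L))
  epochs <- epochTrials(sess$recording)
  res <- rejectArtifactTrials(epochs)
  truthFlags <- trialInfo(sess$truth)$is_artifact
  predFlags <- seq_along(epochs) %in% res$rejected
  expect_gt(mean(predFlags == truthFlags), 0.98)
  # rejected fraction tracks the configured 25% rate
  expect_lt(abs(mean(predFlags) - 0.25), 0.05)
  expect_true(all(c("trial", "reason") %in% names(res$report)))
})

test_that("artifact rejection guards its degenerate cases", {
  set.seed(3)
  epochs <- lapply(1:5, function(i) mkEpoch(matrix(rnorm(3 * 100), 3)))
  res <- rejectArtifactTrials(epochs, zscoreThreshold = 10)
  expect_length(res$rejected, 0L)
  expect_error(rejectArtifactTrials(epochs, zscoreThreshold = 0), "positive")
  expect_error(rejectArtifactTrials(epochs, zscoreThreshold = 1e-9), "all trials")
})

test_that("wavelet denoising preserves shape, audio and trial alignment", {
  sess <- tinySession()
  epochs <- epochTrials(sess$recording)
  cfg <- preprocessConfig()
  den <- waveletDenoise(epochs[[1L]], cfg)
  expect_identical(dim(den), dim(epochs[[1L]]))
  expect_identical(audioSignal(den), audioSignal(epochs[[1L]]))
  expect_identical(stimulusId(den), stimulusId(epochs[[1L]]))
  # pipeline order preserves ground-truth alignment
  prod <- lapply(epochs, function(e)
    extractProductionWindow(waveletDenoise(e, cfg)))
  expect_identical(vapply(prod, stimulusId, 1L), sess$events$stimulus_id)
})

test_that("production window arithmetic matches the protocol", {
  e <- mkEpoch(matrix(rnorm(2 * 5000), 2), audio = rnorm(5000))
  w <- extractProductionWindow(e)
  expect_identical(ncol(sensorData(w)), 2000L)
  expect_identical(sensorData(w)[, 1L], sensorData(e)[, 2501L])
  expect_identical(audioSignal(w), audioSignal(e)[2501:4500])
  expect_identical(w@t0Offset, 2)
  # 4 kHz epoch -> 8000-sample window
  e4 <- new("TrialEpoch", data = matrix(rnorm(2 * 20000), 2), sfreq = 4000,
            t0Offset = -0.5,
            stageMarks = megvad:::protocolStageMarks(4000, -0.5, 20000),
            stimulusId = 1L, audio = numeric(),
            channelNames = c("a", "b"), channelKinds = rep("gradiometer", 2))
  expect_identical(ncol(sensorData(extractProductionWindow(e4))), 8000L)
  noMarks <- e
  noMarks@stageMarks <- rep(NA_integer_, 4)
  names(noMarks@stageMarks) <- names(e@stageMarks)
  expect_error(extractProductionWindow(noMarks), "missing stage marks")
})

test_that("acquisition-rate epochs are resampled to the working rate", {
  t4 <- (0:19999) / 4000
  x <- sin(2 * pi * 30 * t4)
  e4 <- new("TrialEpoch", data = rbind(x, x), sfreq = 4000, t0Offset = -0.5,
            stageMarks = megvad:::protocolStageMarks(4000, -0.5, 20000),
            stimulusId = 1L, audio = numeric(),
            channelNames = c("a", "b"), channelKinds = rep("gradiometer", 2))
  den <- waveletDenoise(e4, preprocessConfig())
  expect_identical(samplingRate(den), 1000)
  expect_identical(ncol(sensorData(den)), 5000L)
  ideal <- sin(2 * pi * 30 * (0:4999) / 1000)
  expect_gt(cor(sensorData(den)[1L, 200:4800], ideal[200:4800]), 0.999)
  expect_identical(stageMarks(den)[["productionCue"]], 2501L)
})

test_that("the worked-example window holds its burst where labeled", {
  we <- workedExample()
  den <- waveletDenoise(we$epoch, preprocessConfig())
  a <- audioSignal(den)
  expect_gt(mean(a[402:931]^2) / mean(a[c(1:401, 932:2000)]^2), 100)
})
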