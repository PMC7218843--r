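test_that("Wiener denoising improves the SNR of a noisy burst", {
  set.seed(12)
  clean <- numeric(2000)
  clean[501:900] <- rnorm(400)  # broadband voiced burst
  noisy <- clean + rnorm(2000)  # white noise at 0 dB within the burst
  snr <- function(x) 10 * log10(sum(clean^2) / sum((x - clean)^2))
  den <- wienerDenoiseAudio(noisy, 1000, smoothing = 0.5)
  expect_gte(snr(den), snr(noisy) + 5)
  # the edge-preserving default still suppresses most of the noise
  expect_gte(snr(wienerDenoiseAudio(noisy, 1000)), snr(noisy) + 3)
})

test_that("Wiener denoising is nearly transparent for clean input", {
  t <- (1:2000) / 1000
  clean <- numeric(2000)
  clean[501:1200] <- sin(2 * pi * 120 * t[501:1200])
  out <- wienerDenoiseAudio(clean, 1000)
  expect_gt(cor(out, clean), 0.99)
  expect_identical(wienerDenoiseAudio(numeric(500), 1000), numeric(500))
  expect_error(wienerDenoiseAudio(rnorm(100), 1000, noiseWindow = c(1, 200)),
               "noise window")
  expect_error(wienerDenoiseAudio(numeric(0), 1000), "empty")
})

test_that("the detector recovers the worked-example boundaries", {
  we <- workedExample()
  d <- detectVoiceActivity(audioSignal(we$epoch), 1000)
  expect_true(d$detected)
  expect_lte(abs(d$onset - 401L), 2L)
  expect_lte(abs(d$offset - 931L), 2L)
  # and still after Wiener denoising
  dw <- detectVoiceActivity(
    wienerDenoiseAudio(audioSignal(we$epoch), 1000), 1000)
  expect_lte(abs(dw$onset - 401L), 2L)
  expect_lte(abs(dw$offset - 931L), 2L)
})

test_that("a silent trial is flagged as no-voice", {
  set.seed(7)
  d <- detectVoiceActivity(rnorm(2000) * 0.05, 1000)
  expect_false(d$detected)
  expect_true(is.na(d$onset))
})

test_that("sub-limit pauses are bridged, longer silences are not", {
  set.seed(9)
  mkBurst <- function(spans) {
    a <- rnorm(2000) * 0.05
    for (sp in spans) a[sp] <- rnorm(length(sp)) * 0.5
    a
  }
  # 150 ms internal pause (< 250 ms) -> one utterance spanning it
  d <- detectVoiceActivity(mkBurst(list(401:700, 851:1150)), 1000)
  expect_lte(abs(d$onset - 400L), 5L)
  expect_lte(abs(d$offset - 1150L), 10L)
  # 400 ms gap -> separate runs; the longest wins
  d2 <- detectVoiceActivity(mkBurst(list(401:550, 951:1500)), 1000)
  expect_lte(abs(d2$onset - 950L), 5L)
  expect_lte(abs(d2$offset - 1500L), 10L)
})

test_that("label partition follows the boundary convention exactly", {
  l <- labelSegments(401, 931, 2000)
  l3 <- labels3(l)
  expect_identical(as.character(l3[1:401]), rep("PRE", 401))
  expect_identical(as.character(l3[402:931]), rep("SPEECH", 530))
  expect_identical(as.character(l3[932:2000]), rep("POST", 1069))
  l2 <- labels2(l)
  expect_identical(as.character(l2[c(1:401, 932:2000)]),
                   rep("NONSPEECH", 401 + 1069))
  expect_identical(as.character(l2[402:931]), rep("SPEECH", 530))
})

test_that("label partition is a contiguous ordered cover for random cases", {
  set.seed(21)
  for (i in 1:50) {
    T <- sample(500:3000, 1)
    onset <- sample(seq_len(T - 2L), 1)
    offset <- sample((onset + 1L):T, 1)
    l <- labelSegments(onset, offset, T)
    counts <- table(labels3(l))
    expect_identical(as.integer(counts[c("PRE", "SPEECH", "POST")]),
                     c(onset, offset - onset, T - offset))
    r <- rle(as.character(labels3(l)))
    expect_true(length(r$values) <= 3L)
    expect_identical(as.character(labels2(l)),
                     as.character(collapseLabels(labels3(l))))
  }
})

test_that("label edge and error cases behave as documented", {
  full <- labelSegments(1, 2000, 2000)  # empty POST edge case
  expect_identical(sum(labels3(full) == "POST"), 0L)
  expect_identical(sum(labels3(full) == "PRE"), 1L)
  expect_error(labelSegments(500, 400, 2000), "onset < offset")
  expect_error(labelSegments(100, 2500, 2000), "exceeds")
  expect_error(labelSegments(0, 400, 2000), "1 <= onset")
})
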