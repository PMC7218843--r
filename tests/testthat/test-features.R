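naiveFramewise <- function(x) {
  t(vapply(seq_len(ncol(x)), function(t) {
    v <- x[, t]
    c(sum(abs(v)), sqrt(mean(v^2)), sqrt(mean(v^2) - mean(v)^2),
      which.max(abs(v)))
  }, numeric(4)))
}

test_that("framewise features match hand arithmetic", {
  f <- featureMatrix(framewiseFeatures(matrix(c(3, -4), 2, 1), sfreq = 1000))
  expect_equal(unname(f[1, ]), c(7, sqrt(12.5), 3.5, 2))
  z <- featureMatrix(framewiseFeatures(matrix(0, 3, 2), sfreq = 1000))
  expect_equal(unname(z[1, ]), c(0, 0, 0, 1))  # tie -> lowest index
  expect_error(framewiseFeatures(matrix(1, 1, 5), sfreq = 1000),
               "two sensors")
  expect_error(framewiseFeatures(matrix(1, 3, 5)), "sfreq")
})

test_that("framewise features agree with the naive per-sample loop", {
  set.seed(14)
  for (i in 1:20) {
    x <- matrix(rnorm(20 * 100), 20)
    fast <- featureMatrix(framewiseFeatures(x, sfreq = 1000))
    slow <- naiveFramewise(x)
    expect_equal(unname(fast), unname(slow), tolerance = 1e-10)
  }
})

test_that("features are scale-equivariant and satisfy the moment bound", {
  set.seed(15)
  x <- matrix(rnorm(10 * 200), 10)
  f1 <- featureMatrix(framewiseFeatures(x, sfreq = 1000))
  f2 <- featureMatrix(framewiseFeatures(3.7 * x, sfreq = 1000))
  expect_equal(f2[, 1:3], 3.7 * f1[, 1:3], tolerance = 1e-12)
  expect_identical(f2[, 4], f1[, 4])
  expect_true(all(f1[, "f2"] >= f1[, "f3"]))
  # equality iff the cross-sensor mean vanishes
  xm <- rbind(1:5, -(1:5))
  fm <- featureMatrix(framewiseFeatures(xm, sfreq = 1000))
  expect_equal(fm[, "f2"], fm[, "f3"], tolerance = 1e-12)
})

test_that("segment RMS features are exact on constructed segments", {
  l <- labelSegments(2, 4, 6)
  x <- rbind(c(5, 5, 3, 4, 1, 1),
             c(-2, -2, 0, 0, 7, 7))
  f <- segmentRmsFeatures(x, l)
  expect_equal(f$PRE, c(5, 2))                    # constant -> |c|
  expect_equal(f$SPEECH[1], sqrt(mean(c(3, 4)^2)))  # sqrt(12.5)
  expect_equal(f$NONSPEECH[2],
               sqrt(mean(c(-2, -2, 7, 7)^2)))     # PRE u POST pooled
  expect_error(segmentRmsFeatures(x[, 1:5], l), "cover")
  expect_error(segmentRmsFeatures(x, labelSegments(1, 6, 6),
                                  classes = "POST"), "empty segment")
})

test_that("speech sensors dominate the speech-segment RMS in the fixture", {
  we <- workedExample()
  tru <- trialInfo(we$truth)
  l <- labelSegments(tru$onset_ms, tru$offset_ms, 2000)
  f <- segmentRmsFeatures(we$epoch, l)
  sp <- speechSensors(we$truth)
  expect_true(all(f$SPEECH[sp] > f$NONSPEECH[sp]))
  # framewise f1 is elevated during speech relative to baseline
  fs <- featureMatrix(framewiseFeatures(we$epoch))
  expect_gt(mean(fs[402:931, "f1"]), 1.5 * mean(fs[1:390, "f1"]))
})

test_that("feature difference standardizes before subtracting", {
  mk <- function(feats) new("FeatureSequence", features = feats,
                            sfreq = 1000, nSensors = 5L)
  v <- rnorm(100)
  same <- mk(cbind(f1 = 10 * v + 3, f2 = abs(v) + 2, f3 = v, f4 = 1))
  expect_equal(featureDifference(same), numeric(100), tolerance = 1e-12)
  const <- mk(cbind(f1 = rep(2, 50), f2 = rep(2, 50), f3 = rep(1, 50),
                    f4 = 1))
  expect_identical(featureDifference(const), numeric(50))
  real <- framewiseFeatures(sensorData(workedExample()$epoch), sfreq = 1000)
  expect_gt(sd(featureDifference(real)), 0)
})

test_that("model input conditioning is as documented", {
  fs <- framewiseFeatures(sensorData(workedExample()$epoch), sfreq = 1000)
  m <- prepareModelInput(fs)
  expect_equal(unname(colMeans(m[, 1:3])), rep(0, 3), tolerance = 1e-12)
  expect_equal(unname(apply(m[, 1:3], 2, sd)), rep(1, 3), tolerance = 1e-12)
  expect_true(all(m[, 4] > 0 & m[, 4] <= 1))
  raw <- prepareModelInput(fs, standardize = "none")
  expect_identical(raw, featureMatrix(fs))
})
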