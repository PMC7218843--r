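bruteMetrics <- function(pred, truth) {
  # independent recomputation straight from the definitions
  tp <- sum(pred == "SPEECH" & truth == "SPEECH")
  tn <- sum(pred == "NONSPEECH" & truth == "NONSPEECH")
  fp <- sum(pred == "SPEECH" & truth == "NONSPEECH")
  fn <- sum(pred == "NONSPEECH" & truth == "SPEECH")
  list(TP = tp, TN = tn, FP = fp, FN = fn,
       accuracy = (tp + tn) / length(pred),
       precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_)
}

test_that("confusion counts and metrics match the defining formulas", {
  p <- speechLabels(11, 15, 20)
  expect_identical(unclass(confusionCounts(p, p))[c("FP", "FN")],
                   list(FP = 0L, FN = 0L))
  expect_equal(countMetrics(confusionCounts(p, p))$accuracy, 1)
  comp <- factor(ifelse(p == "SPEECH", "NONSPEECH", "SPEECH"),
                 levels = c("SPEECH", "NONSPEECH"))
  cc <- confusionCounts(comp, p)
  expect_identical(cc$TP + cc$TN, 0L)
  expect_equal(countMetrics(cc)$accuracy, 0)
  hand <- list(TP = 5L, TN = 3L, FP = 1L, FN = 1L)
  m <- countMetrics(hand)
  expect_equal(m$accuracy, 0.8)
  expect_equal(m$precision, 5 / 6)
  expect_equal(m$recall, 5 / 6)
  expect_error(confusionCounts(p[1:5], p), "equal length")
})

test_that("precision is reported as NA when undefined, never silently 0", {
  allNeg <- factor(rep("NONSPEECH", 10), levels = c("SPEECH", "NONSPEECH"))
  truth <- speechLabels(3, 5, 10)
  m <- countMetrics(confusionCounts(allNeg, truth))
  expect_true(is.na(m$precision))
  expect_equal(m$recall, 0)
})

test_that("accuracy bookkeeping is exact rational arithmetic", {
  set.seed(33)
  for (i in 1:20) {
    n <- sample(50:400, 1)
    pred <- factor(sample(c("SPEECH", "NONSPEECH"), n, TRUE),
                   levels = c("SPEECH", "NONSPEECH"))
    truth <- factor(sample(c("SPEECH", "NONSPEECH"), n, TRUE),
                    levels = c("SPEECH", "NONSPEECH"))
    cc <- confusionCounts(pred, truth)
    tot <- cc$TP + cc$TN + cc$FP + cc$FN
    expect_identical(tot, as.integer(n))
    expect_equal(countMetrics(cc)$accuracy * tot, cc$TP + cc$TN,
                 tolerance = 1e-12)
    expect_identical(round(countMetrics(cc)$accuracy * tot),
                     as.numeric(cc$TP + cc$TN))
  }
})

test_that("per-trial aggregation and micro-averaging are exact", {
  ccA <- list(TP = 8L, TN = 8L, FP = 2L, FN = 2L)   # accuracy 0.8
  ccB <- list(TP = 9L, TN = 9L, FP = 1L, FN = 1L)   # accuracy 0.9
  m <- vadMetrics(list(ccA, ccB))
  expect_equal(m$subjectSummary$mean_accuracy, 0.85)
  expect_equal(m$subjectSummary$sd_accuracy, 0.05)  # population formula
  expect_equal(m$pooled$precision, 17 / 20)
  one <- vadMetrics(list(list(TP = 5L, TN = 5L, FP = 0L, FN = 0L)))
  expect_equal(one$pooled$accuracy, 1)
  expect_equal(one$grandMeanAccuracy, 1)
  expect_error(vadMetrics(list()), "no trials")
})

test_that("micro-averaged pooling equals summed-count metrics on random trials", {
  set.seed(34)
  counts <- lapply(1:30, function(i) {
    pred <- factor(sample(c("SPEECH", "NONSPEECH"), 100, TRUE),
                   levels = c("SPEECH", "NONSPEECH"))
    truth <- speechLabels(sample(20:50, 1), sample(55:90, 1), 100)
    confusionCounts(pred, truth)
  })
  subj <- rep(c("S01", "S02"), 15)
  m <- vadMetrics(counts, subj)
  summed <- list(TP = sum(vapply(counts, `[[`, 1L, "TP")),
                 TN = sum(vapply(counts, `[[`, 1L, "TN")),
                 FP = sum(vapply(counts, `[[`, 1L, "FP")),
                 FN = sum(vapply(counts, `[[`, 1L, "FN")))
  expect_identical(m$pooled, countMetrics(summed))
  # permutation invariance of the pooled metrics
  perm <- sample(30)
  m2 <- vadMetrics(counts[perm], subj[perm])
  expect_identical(m2$pooled, m$pooled)
  expect_equal(sort(m2$subjectSummary$mean_accuracy),
               sort(m$subjectSummary$mean_accuracy))
})

test_that("onset/offset errors are signed, negative when early", {
  truth <- speechLabels(501, 900, 2000)
  early <- speechLabels(491, 890, 2000)
  e <- onsetOffsetErrors(early, truth, 1000)
  expect_equal(e$onset_error_ms, -10)
  expect_equal(e$offset_error_ms, -10)
  same <- onsetOffsetErrors(truth, truth, 1000)
  expect_equal(same$onset_error_ms, 0)
  expect_equal(same$offset_error_ms, 0)
  none <- factor(rep("NONSPEECH", 2000), levels = c("SPEECH", "NONSPEECH"))
  flagged <- onsetOffsetErrors(none, truth, 1000)
  expect_true(flagged$flagged)
  expect_true(is.na(flagged$onset_error_ms))
  expect_error(onsetOffsetErrors(truth, none, 1000), "no SPEECH run")
})

test_that("run selection rules behave as documented", {
  pred <- factor(rep("NONSPEECH", 1000), levels = c("SPEECH", "NONSPEECH"))
  pred[101:120] <- "SPEECH"    # short early run
  pred[501:900] <- "SPEECH"    # the long run
  truth <- speechLabels(496, 905, 1000)
  long <- onsetOffsetErrors(pred, truth, 1000)
  expect_equal(long$onset_error_ms, 5)
  first <- onsetOffsetErrors(pred, truth, 1000, rule = "first")
  expect_equal(first$onset_error_ms, 100 - 495)
  # millisecond conversion respects sfreq
  half <- onsetOffsetErrors(pred, truth, 500)
  expect_equal(half$onset_error_ms, 10)
})

test_that("sensor-mode analysis counts the most-active sensor during speech", {
  mk <- function(f4) new("FeatureSequence",
                         features = cbind(f1 = 1, f2 = 1, f3 = 0, f4 = f4),
                         sfreq = 1000, nSensors = 10L)
  fs <- mk(rep(7, 50))
  sm <- sensorModeAnalysis(list(fs), list(rep(TRUE, 50)))
  expect_identical(sm$pooled, data.frame(sensor = 7L, count = 50L))
  expect_identical(sm$topSensors, 7L)
  empty <- sensorModeAnalysis(list(fs), list(rep(FALSE, 50)))
  expect_identical(nrow(empty$pooled), 0L)
  # per-subject split and binary-label masks
  fs2 <- mk(c(rep(3, 30), rep(4, 20)))
  sm2 <- sensorModeAnalysis(list(fs, fs2), list(rep(TRUE, 50), rep(TRUE, 50)),
                            subjects = c("A", "B"), topK = 2)
  expect_identical(names(sm2$perSubject), c("A", "B"))
  expect_identical(sm2$topSensors, c(7L, 3L))
})

test_that("one-tailed paired t-test matches the closed form", {
  a <- c(30.02, 29.99, 30.11, 29.97, 30.01, 29.99)
  b <- c(29.89, 29.93, 29.72, 29.98, 30.02, 29.98)
  d <- a - b
  tHand <- mean(d) / (sd(d) / sqrt(length(d)))
  res <- oneTailedPairedTTest(a, b, "greater")
  expect_equal(res$statistic, tHand, tolerance = 1e-12)
  expect_equal(res$p.value, pt(tHand, df = 5, lower.tail = FALSE),
               tolerance = 1e-12)
  flip <- oneTailedPairedTTest(a, b, "less")
  expect_equal(res$p.value + flip$p.value, 1, tolerance = 1e-12)
  same <- oneTailedPairedTTest(a, a, "greater")
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 0.5)
  expect_error(oneTailedPairedTTest(a, a + 1, "greater"), "zero variance")
})
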