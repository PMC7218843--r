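# tiny sequence-labeling task: features carry a step during the speech span
mkSeqTask <- function(nTrials, T = 200L, snr = 3, seed = 1) {
  set.seed(seed)
  seqs <- list(); labs <- list()
  for (i in seq_len(nTrials)) {
    onset <- sample(40:70, 1)
    offset <- onset + sample(60:100, 1)
    l <- labelSegments(onset, offset, T)
    base <- matrix(rnorm(T * 3), T)
    bump <- as.numeric(labels2(l) == "SPEECH") * snr
    seqs[[i]] <- cbind(f1 = base[, 1] + bump, f2 = base[, 2] + bump,
                       f3 = base[, 3] + bump, f4 = sample(5, T, TRUE))
    labs[[i]] <- l
  }
  list(seqs = seqs, labs = labs)
}

tinyCfg <- function(maxEpochs = 6L, seed = 42L)
  lstmConfig(nLayers = 2L, hiddenUnits = 8L, maxEpochs = maxEpochs,
             patience = maxEpochs, batchSize = 8L, seed = seed)

test_that("analytic BPTT gradients match finite differences", {
  set.seed(3)
  cfg <- lstmConfig(nLayers = 2L, hiddenUnits = 3L)
  p <- megvad:::initLstmParams(4L, cfg)
  X <- array(rnorm(4 * 2 * 6), c(4, 2, 6))
  y <- factor(sample(c("SPEECH", "NONSPEECH"), 12, TRUE),
              levels = c("SPEECH", "NONSPEECH"))
  Y <- megvad:::oneHot(y)
  lossOf <- function(pp)
    -mean(log(pmax(colSums(megvad:::lstmForward(pp, X)$P * Y), 1e-12)))
  fwd <- megvad:::lstmForward(p, X, cache = TRUE)
  gr <- megvad:::lstmBackward(p, fwd, Y)
  eps <- 1e-6
  worst <- 0
  probe <- function(get, set, g) {
    for (k in seq_len(min(6L, length(g)))) {
      num <- (lossOf(set(eps, k)) - lossOf(set(-eps, k))) / (2 * eps)
      worst <<- max(worst, abs(num - g[k]) /
                      max(abs(num), abs(g[k]), 1e-8))
    }
  }
  for (l in 1:2) for (nm in c("W", "R", "b"))
    probe(NULL, function(e, k) {
      p2 <- p; p2$layers[[l]][[nm]][k] <- p2$layers[[l]][[nm]][k] + e; p2
    }, gr$layers[[l]][[nm]])
  for (nm in c("W", "b"))
    probe(NULL, function(e, k) {
      p2 <- p; p2$head[[nm]][k] <- p2$head[[nm]][k] + e; p2
    }, gr$head[[nm]])
  expect_lt(worst, 1e-3)
})

test_that("training learns a separable sequence task", {
  task <- mkSeqTask(24, seed = 5)
  model <- trainVadLstm(task$seqs[1:20], task$labs[1:20], tinyCfg())
  accs <- vapply(21:24, function(i) {
    p <- predictSequence(model, task$seqs[[i]])
    mean(as.character(p$labels) == as.character(labels2(task$labs[[i]])))
  }, numeric(1))
  expect_gt(mean(accs), 0.9)
  h <- trainingHistory(model)
  expect_true(all(c("epoch", "loss", "val_accuracy") %in% names(h)))
  expect_lt(h$loss[nrow(h)], h$loss[1L])
})

test_that("probabilities are a valid per-sample softmax and inference is deterministic", {
  task <- mkSeqTask(8, seed = 6)
  model <- trainVadLstm(task$seqs[1:6], task$labs[1:6],
                        tinyCfg(maxEpochs = 2L))
  p1 <- predictSequence(model, task$seqs[[7]])
  p2 <- predictSequence(model, task$seqs[[7]])
  expect_identical(p1, p2)
  expect_equal(unname(rowSums(p1$probs)), rep(1, 200), tolerance = 1e-6)
  expect_identical(length(p1$labels), 200L)
})

test_that("seeded training is reproducible and save/load is bit-identical", {
  task <- mkSeqTask(8, seed = 7)
  m1 <- trainVadLstm(task$seqs[1:6], task$labs[1:6], tinyCfg(maxEpochs = 3L))
  m2 <- trainVadLstm(task$seqs[1:6], task$labs[1:6], tinyCfg(maxEpochs = 3L))
  expect_identical(m1@params, m2@params)
  path <- withr::local_tempfile(fileext = ".rds")
  saveVadModel(m1, path)
  m3 <- loadVadModel(path)
  expect_identical(predictSequence(m1, task$seqs[[7]]),
                   predictSequence(m3, task$seqs[[7]]))
  expect_error(loadVadModel({
    junk <- withr::local_tempfile(fileext = ".rds")
    saveRDS(1, junk); junk
  }), "not a model")
})

test_that("degenerate constant-label training predicts that class everywhere", {
  set.seed(8)
  seqs <- lapply(1:6, function(i) matrix(rnorm(150 * 4), 150))
  labs <- lapply(1:6, function(i)
    factor(rep("NONSPEECH", 150), levels = c("SPEECH", "NONSPEECH")))
  model <- trainVadLstm(seqs, labs, tinyCfg(maxEpochs = 12L))
  p <- predictSequence(model, matrix(rnorm(150 * 4), 150))
  expect_true(all(p$labels == "NONSPEECH"))
})

test_that("input validation catches mismatches", {
  task <- mkSeqTask(4, seed = 9)
  shortLab <- task$labs
  shortLab[[2]] <- factor(rep("SPEECH", 100),
                          levels = c("SPEECH", "NONSPEECH"))
  expect_error(trainVadLstm(task$seqs, shortLab, tinyCfg()), "mismatched")
  model <- trainVadLstm(task$seqs, task$labs, tinyCfg(maxEpochs = 1L))
  expect_error(predictSequence(model, matrix(0, 50, 3)),
               "dimensionality")
})

test_that("label-shuffled training stays at chance on held-out trials", {
  task <- mkSeqTask(16, snr = 3, seed = 10)
  shuffled <- lapply(task$labs[1:12], function(l) {
    set.seed(99)
    factor(sample(as.character(labels2(l))),
           levels = c("SPEECH", "NONSPEECH"))
  })
  model <- trainVadLstm(task$seqs[1:12], shuffled, tinyCfg())
  res <- vapply(13:16, function(i) {
    p <- predictSequence(model, task$seqs[[i]])
    truth <- as.character(labels2(task$labs[[i]]))
    c(acc = mean(as.character(p$labels) == truth),
      maj = max(mean(truth == "NONSPEECH"), mean(truth == "SPEECH")))
  }, numeric(2))
  expect_lte(mean(res["acc", ]), mean(res["maj", ]) + 0.05)
})

test_that("held-out accuracy is non-decreasing in SNR", {
  accAt <- function(snr, seed) {
    task <- mkSeqTask(16, snr = snr, seed = seed)
    model <- trainVadLstm(task$seqs[1:12], task$labs[1:12],
                          tinyCfg(seed = seed))
    mean(vapply(13:16, function(i) {
      p <- predictSequence(model, task$seqs[[i]])
      mean(as.character(p$labels) == as.character(labels2(task$labs[[i]])))
    }, numeric(1)))
  }
  means <- vapply(c(0, 1.5, 3), function(s)
    mean(vapply(1:3, function(sd) accAt(s, 100 + sd), numeric(1))),
    numeric(1))
  expect_true(all(diff(means) >= -0.02))
})
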