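# Isolated segment classification: polynomial-kernel SVM with stratified
# cross-validation over the Pre/Speech/Post class pairings.

SVM_PAIRINGS <- c("PRE-vs-POST", "PRE-vs-SPEECH", "POST-vs-SPEECH",
                  "SPEECH-vs-NONSPEECH", "3-CLASS-OVO")

#' SVM configuration
#'
#' A 2nd-order polynomial kernel binary SVM evaluated with stratified 6-fold
#' cross-validation, for each requested pairing of the Pre-Speech, Speech and
#' Post-Speech segments. The three-class task uses one-vs-one voting.
#'
#' @param degree polynomial kernel degree.
#' @param nFolds number of cross-validation folds.
#' @param pairings subset of
#'   `c("PRE-vs-POST","PRE-vs-SPEECH","POST-vs-SPEECH","SPEECH-vs-NONSPEECH",
#'   "3-CLASS-OVO")`.
#' @param cost SVM cost parameter.
#' @param coef0 kernel offset (inhomogeneous polynomial).
#' @param seed RNG seed for the fold assignment.
#' @return list of class `SvmConfig`.
#' @export
svmConfig <- function(degree = 2L, nFolds = 6L, pairings = SVM_PAIRINGS,
                      cost = 1, coef0 = 1, seed = 1L) {
  stopifnot(nFolds >= 2L, degree >= 1L, all(pairings %in% SVM_PAIRINGS))
  structure(list(degree = as.integer(degree), nFolds = as.integer(nFolds),
                 pairings = pairings, cost = cost, coef0 = coef0,
                 seed = as.integer(seed)),
            class = "SvmConfig")
}

stratifiedFolds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

#' Assemble the segment-feature data set
#'
#' One per-sensor RMS feature vector per trial and segment class
#' ([segmentRmsFeatures]), stacked into a design matrix with a class factor,
#' ready for [svmIsolatedClassify].
#'
#' @param epochs list of [TrialEpoch-class] production windows.
#' @param labelsList list of [SegmentLabels-class], one per epoch.
#' @return list with `features` (rows = trial x class) and `labels` (factor
#'   over PRE, SPEECH, POST).
#' @export
segmentFeatureSet <- function(epochs, labelsList) {
  stopifnot(length(epochs) == length(labelsList))
  rows <- list()
  lab <- character()
  for (i in seq_along(epochs)) {
    f <- segmentRmsFeatures(epochs[[i]], labelsList[[i]],
                            classes = c("PRE", "SPEECH", "POST"))
    rows <- c(rows, f)
    lab <- c(lab, names(f))
  }
  list(features = do.call(rbind, rows),
       labels = factor(lab, levels = c("PRE", "SPEECH", "POST")))
}

#' Cross-validated isolated segment classification
#'
#' For each requested pairing, stratified k-fold cross-validation of a
#' polynomial-kernel SVM on per-sensor RMS features. Feature standardization
#' is fit on the training folds only. The `SPEECH-vs-NONSPEECH` pairing
#' relabels `PRE` and `POST` rows as `NONSPEECH`; `3-CLASS-OVO` keeps all
#' three classes (one-vs-one voting).
#'
#' @param features numeric matrix, one row per segment example.
#' @param labels factor over `PRE`, `SPEECH`, `POST` aligned with the rows.
#' @param config an [svmConfig].
#' @return data.frame with `pairing`, `mean_accuracy`, `sd_accuracy` (over
#'   folds), `n_examples`.
#' @export
svmIsolatedClassify <- function(features, labels, config = svmConfig()) {
  stopifnot(inherits(config, "SvmConfig"))
  features <- as.matrix(features)
  labels <- factor(labels, levels = c("PRE", "SPEECH", "POST"))
  stopifnot(nrow(features) == length(labels))

  evalOne <- function(x, y) {
    y <- droplevels(y)
    if (any(table(y) < config$nFolds))
      stop("a class has fewer examples than cross-validation folds")
    fold <- withSeed(config$seed, stratifiedFolds(y, config$nFolds))
    acc <- vapply(seq_len(config$nFolds), function(k) {
      tr <- fold != k
      mu <- colMeans(x[tr, , drop = FALSE])
      sdv <- apply(x[tr, , drop = FALSE], 2L, stats::sd)
      sdv[sdv == 0] <- 1
      xs <- sweep(sweep(x, 2L, mu), 2L, sdv, "/")
      fit <- e1071::svm(xs[tr, , drop = FALSE], y[tr],
                        kernel = "polynomial", degree = config$degree,
                        coef0 = config$coef0, cost = config$cost,
                        scale = FALSE)
      mean(predict(fit, xs[!tr, , drop = FALSE]) == y[!tr])
    }, numeric(1))
    c(mean(acc), stats::sd(acc))
  }

  res <- lapply(config$pairings, function(p) {
    if (p == "3-CLASS-OVO") {
      keep <- rep(TRUE, length(labels)); y <- labels
    } else if (p == "SPEECH-vs-NONSPEECH") {
      keep <- rep(TRUE, length(labels))
      y <- factor(ifelse(labels == "SPEECH", "SPEECH", "NONSPEECH"),
                  levels = c("SPEECH", "NONSPEECH"))
    } else {
      cls <- strsplit(p, "-vs-")[[1L]]
      keep <- labels %in% cls
      y <- factor(labels[keep], levels = cls)
    }
    a <- evalOne(features[keep, , drop = FALSE], y)
    data.frame(pairing = p, mean_accuracy = a[1L], sd_accuracy = a[2L],
               n_examples = sum(keep))
  })
  do.call(rbind, res)
}
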