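#' Subject-wise fold assignment
#'
#' A seeded permutation of the subject ids chunked into `k` near-equal
#' folds (sizes differ by at most one); every window inherits its
#' subject's fold, so no subject ever spans folds.
#'
#' @param subject_ids Character vector of distinct subject ids.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Named integer vector mapping subject id to fold index (1..k).
#' @examples
#' table(assignFolds(sprintf("S%02d", 1:65), k = 5, seed = 1))
#' @export
assignFolds <- function(subject_ids, k = 5L, seed = 1L) {
  subject_ids <- unique(as.character(subject_ids))
  if (length(subject_ids) < k) {
    stopf("need at least k = %d subjects, got %d", k, length(subject_ids))
  }
  perm <- withSeed(seed, sample(subject_ids))
  folds <- rep(seq_len(k), length.out = length(perm))
  folds <- sort(folds)  # chunked: first ceil(n/k) subjects -> fold 1, ...
  stats::setNames(folds[match(subject_ids, perm)], subject_ids)
}

#' Classification metrics report
#'
#' Accuracy, weighted precision and weighted F1 (per-class scores weighted
#' by true-class support), and the confusion matrix both raw and
#' row-normalized per true class. Per-class precision/F1 with an empty
#' predicted class is taken as 0.
#'
#' @param truth Factor of true labels.
#' @param pred Factor of predicted labels (same levels).
#' @return A `MetricsReport` list: `accuracy`, `weighted_precision`,
#'   `weighted_f1`, `confusion` (counts), `confusion_normalized`,
#'   `per_class` data.frame.
#' @examples
#' y <- factor(c("a", "a", "b"), levels = c("a", "b"))
#' evaluateMetrics(y, y)$accuracy
#' @export
evaluateMetrics <- function(truth, pred) {
  if (length(truth) == 0L) stopf("empty test set")
  if (length(truth) != length(pred)) stopf("truth/pred length mismatch")
  truth <- as.factor(truth)
  pred <- factor(as.character(pred), levels = levels(truth))
  cm <- table(truth = truth, pred = pred)
  support <- rowSums(cm)
  tp <- diag(cm)
  prec <- ifelse(colSums(cm) > 0, tp / colSums(cm), 0)
  rec <- ifelse(support > 0, tp / support, 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  wts <- support / sum(support)
  cmn <- sweep(cm, 1L, pmax(support, 1L), "/")
  structure(list(
    accuracy = sum(tp) / sum(cm),
    weighted_precision = sum(wts * prec),
    weighted_f1 = sum(wts * f1),
    confusion = unclass(cm),
    confusion_normalized = unclass(cmn),
    per_class = data.frame(class = rownames(cm), support = as.integer(support),
                           precision = as.numeric(prec),
                           recall = as.numeric(rec), f1 = as.numeric(f1))
  ), class = "MetricsReport")
}

#' @export
print.MetricsReport <- function(x, ...) {
  cat(sprintf("accuracy %.4f | weighted F1 %.4f | weighted precision %.4f\n",
              x$accuracy, x$weighted_f1, x$weighted_precision))
  print(round(x$confusion_normalized, 3))
  invisible(x)
}

foldSplit <- function(folds, i, k) {
  test_f <- i
  val_f <- (i %% k) + 1L
  train_f <- setdiff(seq_len(k), c(test_f, val_f))
  list(
    train = names(folds)[folds %in% train_f],
    val = names(folds)[folds == val_f],
    test = names(folds)[folds == test_f]
  )
}

assertDisjoint <- function(split) {
  if (length(intersect(split$train, split$test)) ||
      length(intersect(split$val, split$test)) ||
      length(intersect(split$train, split$val))) {
    stopf("subject leakage: train/val/test subject sets are not disjoint")
  }
}

wsSubset <- function(ws, subjects) {
  ws[, windowSubjects(ws) %in% subjects]
}

medianFoldIndex <- function(acc) {
  # fold whose test accuracy equals the median order statistic (lower
  # middle for even k); the lowest fold index wins ties
  med <- sort(acc)[ceiling(length(acc) / 2)]
  which(acc == med)[1]
}

#' Subject-wise cross-validation of the FCN
#'
#' For fold i: test = fold i, validation = fold `(i mod k) + 1`, training =
#' the remaining folds. Each fold trains a freshly initialized FCN
#' (seeded), retains its best-validation checkpoint, and is scored on the
#' held-out test fold. Reports per-fold metrics, the mean/sd summary, and
#' the median-performing fold (by test accuracy, lowest index on ties).
#'
#' @param ws A [WindowSet] of filtered windows.
#' @param config An [fcnConfig()].
#' @param folds Fold assignment from [assignFolds()].
#' @param settings A [trainSettings()].
#' @param verbose Print progress.
#' @return List: `fold_reports` (list of `MetricsReport`), `fold_accuracy`,
#'   `median_fold`, `median_report`, `mean_accuracy`, `sd_accuracy`,
#'   `models` (per-fold trained [FcnModel]s), `histories`.
#' @export
crossValidateFcn <- function(ws, config = fcnConfig(), folds,
                             settings = trainSettings(), verbose = FALSE) {
  k <- max(folds)
  X <- SummarizedExperiment::assay(ws, "eda")
  y <- windowLabels(ws)
  subj <- windowSubjects(ws)
  reports <- vector("list", k)
  models <- vector("list", k)
  histories <- vector("list", k)
  for (i in seq_len(k)) {
    sp <- foldSplit(folds, i, k)
    assertDisjoint(sp)
    tr_idx <- subj %in% sp$train
    va_idx <- subj %in% sp$val
    te_idx <- subj %in% sp$test
    model <- buildFcn(config, seed = deriveSeed(settings$seed, 100L + i))
    fit <- trainFcn(model,
                    X[, tr_idx, drop = FALSE], y[tr_idx],
                    X[, va_idx, drop = FALSE], y[va_idx],
                    settings = settings,
                    subjects_train = subj[tr_idx],
                    subjects_val = subj[va_idx],
                    verbose = verbose)
    probs <- predictFcn(fit$model, X[, te_idx, drop = FALSE])
    pred <- painFactor(PAIN_LEVELS[max.col(probs, ties.method = "first")])
    reports[[i]] <- evaluateMetrics(y[te_idx], pred)
    models[[i]] <- fit$model
    histories[[i]] <- fit$history
    if (verbose) {
      message(sprintf("fold %d: test accuracy %.4f (best epoch %d)",
                      i, reports[[i]]$accuracy, fit$best_epoch))
    }
  }
  acc <- vapply(reports, function(r) r$accuracy, numeric(1))
  med <- medianFoldIndex(acc)
  list(
    fold_reports = reports, fold_accuracy = acc,
    median_fold = med, median_report = reports[[med]],
    mean_accuracy = mean(acc), sd_accuracy = sd(acc),
    models = models, histories = histories
  )
}

#' Subject-wise cross-validation of a classical baseline
#'
#' Per fold: features are extracted for all windows, PCA is fitted on the
#' training folds only (no leakage), applied to train and test rows, and
#' the baseline of `spec` is trained and scored. The validation fold is
#' left out of training, mirroring the deep-model protocol.
#'
#' @param feats n x 36 feature matrix (precompute with [featureMatrix()]).
#' @param y Label factor per row.
#' @param subjects Subject id per row.
#' @param spec A [baselineSpec()].
#' @param folds Fold assignment from [assignFolds()].
#' @param k_pca Number of PCA components.
#' @return Same structure as [crossValidateFcn()] minus models/histories.
#' @export
crossValidateBaseline <- function(feats, y, subjects, spec, folds,
                                  k_pca = 12L) {
  k <- max(folds)
  reports <- vector("list", k)
  for (i in seq_len(k)) {
    sp <- foldSplit(folds, i, k)
    assertDisjoint(sp)
    tr_idx <- subjects %in% sp$train
    te_idx <- subjects %in% sp$test
    pca <- fitPca(feats[tr_idx, , drop = FALSE], k = k_pca)
    reports[[i]] <- trainAndEvalBaseline(
      spec,
      applyPca(pca, feats[tr_idx, , drop = FALSE]), y[tr_idx],
      applyPca(pca, feats[te_idx, , drop = FALSE]), y[te_idx],
      subjects_train = subjects[tr_idx], subjects_test = subjects[te_idx]
    )
  }
  acc <- vapply(reports, function(r) r$accuracy, numeric(1))
  med <- medianFoldIndex(acc)
  list(fold_reports = reports, fold_accuracy = acc,
       median_fold = med, median_report = reports[[med]],
       mean_accuracy = mean(acc), sd_accuracy = sd(acc))
}
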