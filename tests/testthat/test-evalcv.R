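test_that("fold assignment is subject-wise, balanced, and seeded", {
  ids <- sprintf("S%02d", 1:65)
  f <- assignFolds(ids, k = 5, seed = 3)
  expect_identical(sort(names(f)), sort(ids))
  expect_true(all(table(f) == 13L))
  expect_identical(f, assignFolds(ids, k = 5, seed = 3))
  expect_false(identical(f, assignFolds(ids, k = 5, seed = 4)))
  # one subject per fold when n == k
  f5 <- assignFolds(sprintf("S%d", 1:5), k = 5, seed = 1)
  expect_identical(sort(as.integer(f5)), 1:5)
  expect_error(assignFolds(sprintf("S%d", 1:4), k = 5), "at least")
  # near-equal sizes when n is not a multiple of k
  f7 <- assignFolds(sprintf("S%d", 1:7), k = 3, seed = 1)
  expect_lte(diff(range(table(f7))), 1L)
})

test_that("metrics match hand-computed values on a printed toy example", {
  # 10 samples, truth (4 NP, 3 LP, 3 HP), all predicted NP:
  # accuracy 0.4; NP precision 0.4, recall 1, F1 4/7; others 0
  truth <- factor(rep(labelLevels, c(4, 3, 3)), levels = labelLevels)
  pred <- factor(rep("NoPain", 10), levels = labelLevels)
  r <- evaluateMetrics(truth, pred)
  expect_equal(r$accuracy, 0.4)
  expect_equal(r$weighted_precision, 0.4 * 0.4)        # only NP contributes
  expect_equal(r$weighted_f1, 0.4 * (2 * 0.4 / 1.4))
  expect_equal(unname(r$confusion_normalized[, "NoPain"]), c(1, 1, 1))
  # perfect prediction: identity confusion
  rp <- evaluateMetrics(truth, truth)
  expect_equal(rp$accuracy, 1)
  expect_equal(unname(diag(rp$confusion_normalized)), c(1, 1, 1))
  # single-class truth: one populated row summing to 1
  r1 <- evaluateMetrics(factor(rep("LowPain", 5), levels = labelLevels),
                        factor(rep("NoPain", 5), levels = labelLevels))
  expect_equal(sum(r1$confusion_normalized["LowPain", ]), 1)
})

test_that("metrics agree with an independent implementation", {
  skip_if_not_installed("caret")
  set.seed(8)
  truth <- factor(sample(labelLevels, 200, replace = TRUE,
                         prob = c(0.5, 0.3, 0.2)), levels = labelLevels)
  pred <- factor(sample(labelLevels, 200, replace = TRUE),
                 levels = labelLevels)
  r <- evaluateMetrics(truth, pred)
  cm <- caret::confusionMatrix(pred, truth)
  expect_equal(r$accuracy, unname(cm$overall["Accuracy"]))
  support <- as.numeric(table(truth)) / length(truth)
  expect_equal(r$weighted_precision,
               sum(support * cm$byClass[, "Precision"], na.rm = TRUE))
  expect_equal(r$weighted_f1,
               sum(support * cm$byClass[, "F1"], na.rm = TRUE))
})

test_that("fold rotation produces disjoint 3/1/1 splits", {
  f <- assignFolds(sprintf("S%02d", 1:10), k = 5, seed = 2)
  for (i in 1:5) {
    sp <- edapain:::foldSplit(f, i, 5)
    expect_length(sp$test, 2L)
    expect_length(sp$val, 2L)
    expect_length(sp$train, 6L)
    expect_length(intersect(sp$train, sp$test), 0L)
    expect_length(intersect(sp$val, sp$test), 0L)
    expect_length(intersect(sp$train, sp$val), 0L)
    expect_identical(unname(unique(f[sp$val])), (i %% 5L) + 1L)
  }
})

test_that("median fold selection uses the middle order statistic, ties low", {
  expect_identical(edapain:::medianFoldIndex(c(0.5, 0.9, 0.7, 0.6, 0.8)), 3L)
  expect_identical(edapain:::medianFoldIndex(rep(0.5, 5)), 1L)
  expect_identical(edapain:::medianFoldIndex(c(0.9, 0.5, 0.9, 0.9, 0.5)), 1L)
})

test_that("training stops early and reproduces histories under a fixed seed", {
  cfg <- tinyFcnConfig()
  set.seed(4)
  X <- matrix(rnorm(40 * 30), 40, 30)
  y <- factor(sample(labelLevels, 30, replace = TRUE), levels = labelLevels)
  m <- buildFcn(cfg, seed = 1)
  st <- trainSettings(max_epochs = 50, patience = 2, learning_rate = 1e-3,
                      batch_size = 8, seed = 6)
  # constant data: validation accuracy cannot improve after epoch 1
  Xc <- matrix(1, 40, 30)
  fit_c <- trainFcn(m, Xc, y, Xc, y, settings = st)
  expect_lte(nrow(fit_c$history), 1 + fit_c$best_epoch + st$patience)
  # determinism
  f1 <- trainFcn(m, X, y, X[, 1:10], y[1:10],
                 settings = trainSettings(max_epochs = 3, patience = 2,
                                          batch_size = 8, seed = 6))
  f2 <- trainFcn(m, X, y, X[, 1:10], y[1:10],
                 settings = trainSettings(max_epochs = 3, patience = 2,
                                          batch_size = 8, seed = 6))
  expect_identical(f1$history, f2$history)
  expect_identical(f1$model@params, f2$model@params)
  # best checkpoint is never worse than any epoch's validation accuracy
  expect_gte(f1$best_val_acc, max(f1$history$val_acc) - 1e-12)
})

test_that("leakage between train and validation subjects is rejected", {
  cfg <- tinyFcnConfig()
  m <- buildFcn(cfg, seed = 1)
  X <- matrix(rnorm(40 * 6), 40, 6)
  y <- factor(rep(labelLevels, 2), levels = labelLevels)
  expect_error(
    trainFcn(m, X, y, X, y, settings = trainSettings(max_epochs = 2,
                                                     patience = 1),
             subjects_train = c("A", "B"), subjects_val = c("A", "C")),
    "leakage")
  expect_error(
    trainFcn(m, X[, 0], y[0], X, y,
             settings = trainSettings(max_epochs = 2, patience = 1)),
    "empty")
})

test_that("baseline cross-validation refits PCA per fold without leakage", {
  co <- generateCohort(synthConfig(n_subjects = 5, seed = 3))
  ws <- buildWindowSet(co)
  feats <- featureMatrix(ws)
  y <- windowLabels(ws)
  subj <- windowSubjects(ws)
  folds <- assignFolds(unique(subj), k = 5, seed = 1)
  cv <- crossValidateBaseline(feats, y, subj, baselineSpec("LDA"), folds,
                              k_pca = 12L)
  expect_length(cv$fold_reports, 5L)
  expect_true(all(cv$fold_accuracy >= 0 & cv$fold_accuracy <= 1))
  expect_identical(cv$median_report$accuracy,
                   cv$fold_accuracy[cv$median_fold])
  expect_gt(cv$mean_accuracy, 1 / 3)  # separable synthetic features
})
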