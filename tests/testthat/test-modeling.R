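test_that("stratified folds are balanced, partitioning, and reproducible", {
  y <- rep(c(0L, 1L), each = 5)
  folds <- stratified_kfold(y, folds = 5, seed = 1)
  for (f in folds) {
    expect_length(f$test, 2L)
    expect_equal(sum(y[f$test]), 1L)  # 1 positive + 1 negative each
    expect_equal(sort(c(f$train, f$test)), seq_along(y))
  }
  tests <- unlist(lapply(folds, `[[`, "test"))
  expect_equal(sort(tests), seq_along(y))  # partition, no overlap

  y2 <- rep(c(0L, 1L), c(70, 30))
  f1 <- stratified_kfold(y2, 5, seed = 9)
  f2 <- stratified_kfold(y2, 5, seed = 9)
  expect_identical(f1, f2)
  f3 <- stratified_kfold(y2, 5, seed = 10)
  expect_false(identical(f1, f3))
  ## per-fold class ratios within one sample of 70/30
  for (f in f1) {
    expect_equal(sum(y2[f$test] == 1L), 6L)
    expect_equal(sum(y2[f$test] == 0L), 14L)
  }

  expect_error(stratified_kfold(rep(c(0L, 1L), c(50, 3)), 5, 1),
               class = "dpp_argument_error")
})

test_that("confusion counts use a strict threshold and partition samples", {
  cc <- confusion(c(1L, 0L), c(0.9, 0.1))
  expect_equal(unlist(cc[c("TP", "TN", "FP", "FN")]),
               c(TP = 1L, TN = 1L, FP = 0L, FN = 0L))

  ## probability exactly at the threshold is a negative call
  cc <- confusion(c(1L, 0L), c(0.5, 0.5), threshold = 0.5)
  expect_equal(cc$FN, 1L)
  expect_equal(cc$TN, 1L)

  cc <- confusion(c(1L, 1L, 0L, 0L, 1L), c(.9, .4, .6, .2, .7))
  expect_equal(unlist(cc[c("TP", "FN", "FP", "TN")]),
               c(TP = 2L, FN = 1L, FP = 1L, TN = 1L))

  expect_error(confusion(c(1L, 0L), 0.4), class = "dpp_argument_error")
  expect_error(confusion(1L, 1.4), class = "dpp_validation_error")
})

test_that("metrics match their closed forms over enumerated counts", {
  m <- classification_metrics(list(TP = 5L, TN = 5L, FP = 0L, FN = 0L))
  expect_equal(unname(m), c(1, 1, 1, 1))
  m <- classification_metrics(list(TP = 3L, FP = 1L, FN = 2L, TN = 4L))
  expect_equal(m[["acc"]], 0.7)
  expect_equal(m[["pre"]], 0.75)
  expect_equal(m[["rec"]], 0.6)
  expect_equal(m[["f1"]], 2 * 0.75 * 0.6 / 1.35)

  ## enumerate a grid and check identities + conventions
  for (TP in 0:3) for (FP in 0:3) for (FN in 0:3) for (TN in 0:3) {
    if (TP + FP + FN + TN == 0) next
    m <- classification_metrics(list(TP = TP, TN = TN, FP = FP, FN = FN))
    expect_true(all(m >= 0 & m <= 1))
    if (m[["pre"]] + m[["rec"]] > 0) {
      expect_equal(m[["f1"]],
                   2 * m[["pre"]] * m[["rec"]] / (m[["pre"]] + m[["rec"]]))
    } else {
      expect_equal(m[["f1"]], 0)
    }
    ## accuracy invariant under swapping the two classes
    ms <- classification_metrics(list(TP = TN, TN = TP, FP = FN, FN = FP))
    expect_equal(m[["acc"]], ms[["acc"]])
  }
})

test_that("AUC equals the exhaustive concordant-pair statistic", {
  expect_equal(roc_auc(c(1L, 1L, 0L, 0L), c(.9, .8, .2, .1)), 1)
  expect_equal(roc_auc(c(1L, 0L, 1L, 0L), rep(0.3, 4)), 0.5)
  expect_equal(roc_auc(c(1L, 0L, 1L, 0L), c(0.9, 0.8, 0.4, 0.3)), 0.75)

  set.seed(31)
  for (i in 1:25) {
    n <- sample(4:200, 1)
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) next
    p <- round(runif(n), 2)  # coarse scores force ties
    expect_equal(roc_auc(y, p), oracle_auc(y, p))
  }
  expect_error(roc_auc(c(1L, 1L), c(.2, .3)), class = "dpp_data_error")
})

test_that("AUC and ROC integration agree with pROC on a random case", {
  set.seed(12)
  y <- rbinom(120, 1, 0.5)
  p <- runif(120)
  expect_equal(roc_auc(y, p),
               as.numeric(pROC::auc(pROC::roc(
                 y, p, quiet = TRUE, direction = "<", levels = c(0, 1)))))
  rp <- roc_points(y, p)
  ## trapezoidal integration of the exported curve reproduces the statistic
  expect_equal(sum(diff(rp$fpr) * (head(rp$tpr, -1) + tail(rp$tpr, -1)) / 2),
               roc_auc(y, p), tolerance = 1e-12)
})

test_that("training handles separable data and rejects degenerate input", {
  pos <- vapply(1:25, function(i) paste(rep("P", 7), collapse = ""), "")
  neg <- vapply(1:25, function(i) paste(rep("E", 7), collapse = ""), "")
  X <- pseaac_matrix(c(pos, neg))
  y <- rep(c(1L, 0L), each = 25)
  for (fam in c("lightgbm", "random_forest")) {
    fit <- train_model(model_spec(fam, seed = 1), X, y)
    cc <- confusion(y, predict_proba(fit, X))
    expect_equal(classification_metrics(cc)[["acc"]], 1)
  }
  expect_error(train_model(model_spec("lightgbm"), X, rep(1L, 50)),
               class = "dpp_data_error")
  Xna <- X; Xna[1, 1] <- NA
  expect_error(train_model(model_spec("lightgbm"), Xna, y),
               class = "dpp_validation_error")
  expect_error(model_spec("lightgbm", list(bogus = 1)),
               class = "dpp_argument_error")
})

test_that("cross-validation is deterministic and benchmark shares folds", {
  set <- generate_labeled_set(synth_config(n_pos = 60, n_neg = 60, seed = 5))
  X <- pseaac_matrix(set$sequence)
  spec <- model_spec("lightgbm", seed = 7)
  r1 <- cross_validate(spec, X, set$label, folds = 5, seed = 7)
  r2 <- cross_validate(spec, X, set$label, folds = 5, seed = 7)
  expect_identical(r1$per_fold, r2$per_fold)
  expect_equal(nrow(r1$per_fold), 5L)
  expect_true(all(r1$per_fold$auc >= 0 & r1$per_fold$auc <= 1))

  bench <- benchmark_models(list(a = spec, b = spec), X, set$label,
                            folds = 5, seed = 7)
  expect_identical(bench$reports$a$per_fold, bench$reports$b$per_fold)
  expect_identical(bench$reports$a$per_fold, r1$per_fold)
})
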