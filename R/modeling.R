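MODEL_FAMILIES <- c("gbdt", "xgboost", "lightgbm", "catboost", "random_forest")

## Published hyperparameter sets for the five benchmarked families.
default_hyperparameters <- function(family) {
  switch(family,
    gbdt = list(n_estimators = 200L, learning_rate = 0.1, max_depth = 3L),
    xgboost = list(n_estimators = 100L, learning_rate = 0.01, max_depth = 5L,
                   alpha = 10),
    lightgbm = list(n_estimators = 100L, learning_rate = 0.05,
                    num_leaves = 31L, max_bin = 255L),
    catboost = list(iterations = 1000L, learning_rate = 0.05, depth = 6L),
    random_forest = list(n_trees = 150L, max_features = "sqrt")
  )
}

#' Specify a classifier configuration
#'
#' A model spec names one of the five benchmarked ensemble families with
#' its hyperparameters and seed. Defaults are the benchmark settings:
#' GBDT 200 trees / lr 0.1; XGBoost max_depth 5 / lr 0.01 / alpha 10;
#' LightGBM-style leaf-wise boosting num_leaves 31 / lr 0.05 / max_bin 255;
#' CatBoost-style depth-6 boosting lr 0.05 / 1000 iterations; random forest
#' 150 trees / sqrt feature sampling.
#'
#' The gradient-boosting families are adapters over the xgboost backend
#' (the `lightgbm` family uses its leaf-wise histogram grower, the
#' `catboost` family its depth-wise grower at the published depth);
#' `random_forest` is backed by ranger. The harness — folds, thresholds,
#' metrics, seeds — is backend-independent, so reports are comparable.
#'
#' @param family One of `"gbdt"`, `"xgboost"`, `"lightgbm"`, `"catboost"`,
#'   `"random_forest"`.
#' @param hyperparameters Named list overriding the family defaults.
#' @param seed Integer seed recorded in every report.
#' @return A `model_spec` object.
#' @export
model_spec <- function(family = MODEL_FAMILIES, hyperparameters = list(),
                       seed = 1L) {
  family <- match.arg(family)
  hp <- utils::modifyList(default_hyperparameters(family), hyperparameters)
  known <- names(default_hyperparameters(family))
  bad <- setdiff(names(hp), known)
  if (length(bad) > 0L) {
    stop_dpp(sprintf("unknown hyperparameter(s) for %s: %s",
                     family, paste(bad, collapse = ", ")),
             "dpp_argument_error")
  }
  structure(list(family = family, hyperparameters = hp,
                 seed = as.integer(seed)),
            class = "model_spec")
}

#' The five benchmark model configurations
#'
#' @param seed Seed shared by all five specs.
#' @return Named list of [model_spec()] objects.
#' @export
benchmark_model_specs <- function(seed = 1L) {
  specs <- lapply(MODEL_FAMILIES, model_spec, seed = seed)
  names(specs) <- MODEL_FAMILIES
  specs
}

check_training_input <- function(X, y) {
  X <- as.matrix(X)
  if (nrow(X) != length(y)) {
    stop_dpp("nrow(X) must equal length(y)", "dpp_argument_error")
  }
  if (any(!is.finite(X))) {
    stop_dpp("X contains non-finite values", "dpp_validation_error")
  }
  if (!all(y %in% c(0L, 1L))) {
    stop_dpp("y must be 0/1 labels", "dpp_validation_error")
  }
  if (length(unique(y)) < 2L) {
    stop_dpp("training labels contain a single class", "dpp_data_error")
  }
  X
}

xgb_params <- function(spec) {
  hp <- spec$hyperparameters
  base <- list(objective = "binary:logistic", nthread = 1L,
               seed = spec$seed)
  switch(spec$family,
    gbdt = c(base, list(eta = hp$learning_rate, max_depth = hp$max_depth,
                        tree_method = "exact")),
    xgboost = c(base, list(eta = hp$learning_rate, max_depth = hp$max_depth,
                           alpha = hp$alpha, tree_method = "exact")),
    lightgbm = c(base, list(eta = hp$learning_rate, tree_method = "hist",
                            grow_policy = "lossguide",
                            max_leaves = hp$num_leaves, max_depth = 0L,
                            max_bin = hp$max_bin)),
    catboost = c(base, list(eta = hp$learning_rate, max_depth = hp$depth,
                            tree_method = "hist"))
  )
}

xgb_nrounds <- function(spec) {
  hp <- spec$hyperparameters
  as.integer(hp$n_estimators %||% hp$iterations)
}

#' Train a classifier from a model spec
#'
#' Fits the configured family on a feature matrix and 0/1 labels and
#' returns an opaque fitted handle exposing probability prediction via
#' [predict_proba()]. Training is deterministic given `(spec$seed, X, y)`
#' for a fixed backend version.
#'
#' @param spec A [model_spec()].
#' @param X Numeric feature matrix (rows = samples).
#' @param y Integer 0/1 labels.
#' @return A `dpp_fit` object.
#' @export
train_model <- function(spec, X, y) {
  stopifnot(inherits(spec, "model_spec"))
  X <- check_training_input(X, y)
  fit <- if (spec$family == "random_forest") {
    df <- as.data.frame(X)
    df$.label <- factor(y, levels = c(0L, 1L))
    with_seed(spec$seed,
      ranger::ranger(
        dependent.variable.name = ".label", data = df,
        num.trees = spec$hyperparameters$n_trees,
        mtry = floor(sqrt(ncol(X))),
        probability = TRUE, num.threads = 1L, seed = spec$seed
      )
    )
  } else {
    dtrain <- xgboost::xgb.DMatrix(X, label = y, nthread = 1L)
    with_seed(spec$seed,
      xgboost::xgb.train(params = xgb_params(spec), data = dtrain,
                         nrounds = xgb_nrounds(spec), verbose = 0)
    )
  }
  structure(list(spec = spec, fit = fit, n_features = ncol(X),
                 feature_names = colnames(X)),
            class = "dpp_fit")
}

#' Predict class-1 probabilities from a fitted classifier
#'
#' @param fit A `dpp_fit` from [train_model()].
#' @param X Feature matrix with the same columns used in training.
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
predict_proba <- function(fit, X) {
  stopifnot(inherits(fit, "dpp_fit"))
  X <- as.matrix(X)
  if (ncol(X) != fit$n_features) {
    stop_dpp(sprintf("feature mismatch: model expects %d columns, got %d",
                     fit$n_features, ncol(X)), "dpp_validation_error")
  }
  if (fit$spec$family == "random_forest") {
    p <- stats::predict(fit$fit, data = as.data.frame(X),
                        num.threads = 1L)$predictions
    unname(p[, "1"])
  } else {
    unname(stats::predict(fit$fit, xgboost::xgb.DMatrix(X, nthread = 1L)))
  }
}

#' Stratified k-fold assignment
#'
#' Partitions samples into `folds` test sets preserving the class ratio
#' (per-fold class counts within one sample of proportionality). The
#' assignment is a deterministic function of `(y, folds, seed)`.
#'
#' @param y Integer 0/1 labels.
#' @param folds Number of folds (default 5).
#' @param seed Integer seed.
#' @return List of `folds` elements, each `list(train =, test =)` index
#'   vectors; the test sets partition `seq_along(y)`.
#' @export
stratified_kfold <- function(y, folds = 5L, seed = 1L) {
  folds <- as.integer(folds)
  if (folds < 2L) stop_dpp("`folds` must be >= 2", "dpp_argument_error")
  counts <- table(factor(y, levels = c(0L, 1L)))
  if (any(counts < folds)) {
    stop_dpp(sprintf(
      "each class needs >= %d members for %d-fold CV (have %s)",
      folds, folds, paste(counts, collapse = "/")), "dpp_argument_error")
  }
  assignment <- integer(length(y))
  with_seed(seed, {
    for (cl in c(0L, 1L)) {
      idx <- which(y == cl)
      idx <- sample(idx)
      assignment[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  lapply(seq_len(folds), function(f) {
    list(train = which(assignment != f), test = which(assignment == f))
  })
}

#' Confusion counts at a probability threshold
#'
#' A sample is called positive iff its probability is strictly greater
#' than the threshold (a probability of exactly 0.5 at the default
#' threshold is a negative call, matching the "greater than 50%" screening
#' gate).
#'
#' @param y_true Integer 0/1 labels.
#' @param y_prob Probabilities in `[0, 1]`.
#' @param threshold Decision threshold (default 0.5).
#' @return List with integer fields `TP`, `TN`, `FP`, `FN`.
#' @export
confusion <- function(y_true, y_prob, threshold = 0.5) {
  if (length(y_true) != length(y_prob)) {
    stop_dpp("y_true and y_prob must have equal length", "dpp_argument_error")
  }
  if (any(y_prob < 0 | y_prob > 1)) {
    stop_dpp("probabilities must lie in [0, 1]", "dpp_validation_error")
  }
  pred <- y_prob > threshold
  structure(list(
    TP = sum(pred & y_true == 1L),
    TN = sum(!pred & y_true == 0L),
    FP = sum(pred & y_true == 0L),
    FN = sum(!pred & y_true == 1L)
  ), class = "confusion_counts")
}

#' Classification metrics from confusion counts
#'
#' Accuracy, recall, precision and F1 in `[0, 1]`:
#' `Acc = (TP+TN)/total`, `Rec = TP/(TP+FN)`, `Pre = TP/(TP+FP)`,
#' `F1 = 2*Pre*Rec/(Pre+Rec)`. Zero-denominator conventions: `Pre = 0`
#' when no positive calls, `Rec = 0` when no positive labels, `F1 = 0`
#' when `Pre + Rec = 0`, keeping every report total.
#'
#' @param counts A `confusion_counts` object (or list with TP/TN/FP/FN).
#' @return Named numeric vector `(acc, rec, pre, f1)`.
#' @export
classification_metrics <- function(counts) {
  TP <- counts$TP; TN <- counts$TN; FP <- counts$FP; FN <- counts$FN
  total <- TP + TN + FP + FN
  if (total == 0L) stop_dpp("empty confusion counts", "dpp_argument_error")
  acc <- (TP + TN) / total
  rec <- if (TP + FN == 0L) 0 else TP / (TP + FN)
  pre <- if (TP + FP == 0L) 0 else TP / (TP + FP)
  f1 <- if (pre + rec == 0) 0 else 2 * pre * rec / (pre + rec)
  c(acc = acc, rec = rec, pre = pre, f1 = f1)
}

#' Area under the ROC curve
#'
#' The rank-statistic (Mann-Whitney) definition: the probability that a
#' random positive outranks a random negative, ties counted one half —
#' identical to trapezoidal integration of the ROC curve.
#'
#' @param y_true Integer 0/1 labels (both classes present).
#' @param y_prob Scores or probabilities.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(y_true, y_prob) {
  if (length(y_true) != length(y_prob)) {
    stop_dpp("y_true and y_prob must have equal length", "dpp_argument_error")
  }
  n1 <- sum(y_true == 1L)
  n0 <- sum(y_true == 0L)
  if (n1 == 0L || n0 == 0L) {
    stop_dpp("AUC undefined: both classes must be present", "dpp_data_error")
  }
  r <- rank(y_prob, ties.method = "average")
  (sum(r[y_true == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve points
#'
#' False/true positive rates over all score thresholds, for export or
#' plotting.
#'
#' @inheritParams roc_auc
#' @return Tibble with columns `threshold`, `fpr`, `tpr`.
#' @export
roc_points <- function(y_true, y_prob) {
  ord <- order(y_prob, decreasing = TRUE)
  y <- y_true[ord]
  p <- y_prob[ord]
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  tp <- cumsum(y == 1L)
  fp <- cumsum(y == 0L)
  keep <- c(p[-1] != p[-length(p)], TRUE)  # one point per distinct score
  tibble::tibble(
    threshold = c(Inf, p[keep]),
    fpr = c(0, fp[keep] / n0),
    tpr = c(0, tp[keep] / n1)
  )
}

#' Cross-validate one model configuration
#'
#' Runs stratified k-fold cross-validation: for each fold the model is
#' trained on the remaining folds and evaluated on the held-out fold with
#' accuracy, recall, precision, F1 (at the strict 0.5 threshold) and AUC.
#'
#' @param spec A [model_spec()].
#' @param X Feature matrix.
#' @param y Integer 0/1 labels.
#' @param folds Number of folds (default 5) or a precomputed fold list
#'   from [stratified_kfold()].
#' @param seed Seed for the fold assignment.
#' @param threshold Decision threshold for the count-based metrics.
#' @return A `cv_report`: list with `per_fold` (tibble of fold metrics),
#'   `summary` (mean and SD per metric), `spec`, `seed`, and per-fold
#'   held-out scores (`fold_scores`) for ROC export.
#' @export
cross_validate <- function(spec, X, y, folds = 5L, seed = 1L,
                           threshold = 0.5) {
  X <- check_training_input(X, y)
  fold_list <- if (is.list(folds)) folds else stratified_kfold(y, folds, seed)
  per_fold <- vector("list", length(fold_list))
  fold_scores <- vector("list", length(fold_list))
  for (f in seq_along(fold_list)) {
    tr <- fold_list[[f]]$train
    te <- fold_list[[f]]$test
    fit <- train_model(spec, X[tr, , drop = FALSE], y[tr])
    prob <- predict_proba(fit, X[te, , drop = FALSE])
    m <- classification_metrics(confusion(y[te], prob, threshold))
    per_fold[[f]] <- tibble::tibble(
      fold = f, acc = m[["acc"]], rec = m[["rec"]], pre = m[["pre"]],
      f1 = m[["f1"]], auc = roc_auc(y[te], prob)
    )
    fold_scores[[f]] <- tibble::tibble(fold = f, y_true = y[te],
                                       y_prob = prob)
  }
  per_fold <- dplyr::bind_rows(per_fold)
  metric_cols <- c("acc", "rec", "pre", "f1", "auc")
  summary <- tibble::tibble(
    metric = metric_cols,
    mean = vapply(metric_cols, function(m) mean(per_fold[[m]]), numeric(1)),
    sd = vapply(metric_cols, function(m) stats::sd(per_fold[[m]]), numeric(1))
  )
  structure(list(per_fold = per_fold, summary = summary, spec = spec,
                 seed = seed, threshold = threshold,
                 fold_scores = dplyr::bind_rows(fold_scores)),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %s, %d folds, seed %d\n", x$spec$family,
              nrow(x$per_fold), x$seed))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-4s %6.2f +/- %.2f\n", s$metric[i], 100 * s$mean[i],
                100 * s$sd[i]))
  }
  invisible(x)
}

#' Benchmark several model configurations on identical folds
#'
#' Cross-validates every spec on the same stratified fold assignment and
#' tabulates mean and SD per metric, so families are compared on exactly
#' the same train/test splits.
#'
#' @param specs List of [model_spec()] objects (default: the five
#'   benchmark configurations).
#' @param X Feature matrix.
#' @param y Integer 0/1 labels.
#' @param folds Number of folds (default 5).
#' @param seed Seed for the shared fold assignment.
#' @return List with `reports` (named list of `cv_report`s) and
#'   `comparison` (tibble: family, metric, mean, sd).
#' @export
benchmark_models <- function(specs = benchmark_model_specs(), X, y,
                             folds = 5L, seed = 1L) {
  if (length(specs) == 0L) {
    stop_dpp("`specs` must contain at least one model", "dpp_argument_error")
  }
  X <- check_training_input(X, y)
  fold_list <- stratified_kfold(y, folds, seed)
  reports <- lapply(specs, function(sp) {
    cross_validate(sp, X, y, folds = fold_list, seed = seed)
  })
  if (is.null(names(reports))) {
    names(reports) <- vapply(specs, function(s) s$family, character(1))
  }
  comparison <- purrr::map_dfr(names(reports), function(nm) {
    s <- reports[[nm]]$summary
    tibble::tibble(family = nm, metric = s$metric, mean = s$mean, sd = s$sd)
  })
  list(reports = reports, comparison = comparison)
}
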