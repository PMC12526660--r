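MODEL_NAMES <- c("linear", "decision_tree", "random_forest",
                 "grad_boost_a", "grad_boost_b")

default_hyper <- function(model_name) {
  switch(model_name,
    linear        = list(),
    decision_tree = list(cp = 0.001, maxdepth = 30, minsplit = 20),
    # the tuned forest architecture: 111 trees, max depth 26
    random_forest = list(num_trees = 111, max_depth = 26, mtry = NULL,
                         min_node_size = 5),
    grad_boost_a  = list(nrounds = 300, eta = 0.1, max_depth = 6,
                         subsample = 1),
    grad_boost_b  = list(nrounds = 300, eta = 0.1, max_depth = 6,
                         subsample = 1, rate_drop = 0.1),
    abort(sprintf("Unknown model `%s`.", model_name),
          class = "hrvpipe_invalid_parameter"))
}

resolve_hyper <- function(model_name, hyperparameters) {
  def <- default_hyper(model_name)
  unknown <- setdiff(names(hyperparameters), names(def))
  if (length(unknown) > 0L) {
    abort(sprintf("Unknown hyperparameter(s) for %s: %s", model_name,
                  paste(unknown, collapse = ", ")),
          class = "hrvpipe_invalid_parameter")
  }
  utils::modifyList(def, hyperparameters)
}

model_features <- function(data, target) {
  setdiff(names(data)[vapply(data, is.numeric, logical(1))],
          c(target, "target", "target_raw"))
}

#' Stratified train/test split
#'
#' Reproducible disjoint split, stratified on quantile bins of the target so
#' the test set mirrors the target distribution. Tables too small to
#' stratify fall back to a plain random split with a warning.
#'
#' @param data A data frame with the target column.
#' @param test_frac Test fraction in (0, 1); default 0.2.
#' @param seed Integer seed.
#' @param target Stratification column (default `"target"`).
#' @param n_bins Number of quantile strata (default 5).
#' @return A list with tibbles `train` and `test`.
#' @export
split_train_test <- function(data, test_frac = 0.2, seed = 42L,
                             target = "target", n_bins = 5L) {
  assert_scalar_number(test_frac, "test_frac",
                       lower = 1e-9, upper = 1 - 1e-9)
  assert_columns(data, target, "data")
  n <- nrow(data)
  with_local_seed(seed, {
    if (n < 5 * n_bins) {
      warn("Table too small to stratify; using a plain random split.")
      bins <- rep(1L, n)
    } else {
      br <- unique(quantile(data[[target]], probs = seq(0, 1, length.out = n_bins + 1)))
      bins <- cut(data[[target]], breaks = br, include.lowest = TRUE,
                  labels = FALSE)
    }
    test_idx <- unlist(lapply(split(seq_len(n), bins), function(rows) {
      k <- round(length(rows) * test_frac)
      if (k == 0L) return(integer())
      sample(rows, k)
    }), use.names = FALSE)
  })
  list(train = data[setdiff(seq_len(n), test_idx), , drop = FALSE],
       test  = data[sort(test_idx), , drop = FALSE])
}

#' Fit one regression model
#'
#' Supported models: `linear` (ordinary least squares), `decision_tree`
#' (CART via rpart), `random_forest` (ranger, impurity importances), and two
#' gradient-boosting variants from xgboost -- `grad_boost_a` (gbtree
#' booster) and `grad_boost_b` (DART booster). Unknown hyperparameter names
#' are rejected; all fits are deterministic under a fixed seed
#' (single-threaded).
#'
#' @param train Training tibble (numeric features plus the target column).
#' @param model_name One of `"linear"`, `"decision_tree"`,
#'   `"random_forest"`, `"grad_boost_a"`, `"grad_boost_b"`.
#' @param hyperparameters Named list overriding the model's defaults.
#' @param seed Integer seed.
#' @param features Feature columns; defaults to every numeric column except
#'   the targets.
#' @param target Response column (default `"target"`).
#' @return An object of class `hrv_model`.
#' @export
fit_regressor <- function(train, model_name, hyperparameters = list(),
                          seed = 42L, features = NULL, target = "target") {
  stopifnot(model_name %in% MODEL_NAMES)
  hp <- resolve_hyper(model_name, hyperparameters)
  features <- features %||% model_features(train, target)
  assert_columns(train, c(features, target), "train")
  x <- as.matrix(train[, features, drop = FALSE])
  y <- train[[target]]
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    abort("Non-finite values in the training data.",
          class = "hrvpipe_invalid_parameter")
  }
  fml <- stats::reformulate(features, response = target)
  fit <- switch(model_name,
    linear = stats::lm(fml, data = train),
    decision_tree = rpart::rpart(
      fml, data = train, method = "anova",
      control = rpart::rpart.control(cp = hp$cp, maxdepth = hp$maxdepth,
                                     minsplit = hp$minsplit)),
    random_forest = ranger::ranger(
      x = x, y = y, num.trees = hp$num_trees, max.depth = hp$max_depth,
      mtry = hp$mtry, min.node.size = hp$min_node_size,
      importance = "impurity", seed = seed, num.threads = 1),
    grad_boost_a = xgboost::xgb.train(
      params = list(booster = "gbtree", eta = hp$eta,
                    max_depth = hp$max_depth, subsample = hp$subsample,
                    objective = "reg:squarederror", nthread = 1, seed = seed),
      data = xgboost::xgb.DMatrix(x, label = y, nthread = 1),
      nrounds = hp$nrounds, verbose = 0),
    grad_boost_b = xgboost::xgb.train(
      params = list(booster = "dart", eta = hp$eta,
                    max_depth = hp$max_depth, subsample = hp$subsample,
                    rate_drop = hp$rate_drop, objective = "reg:squarederror",
                    nthread = 1, seed = seed),
      data = xgboost::xgb.DMatrix(x, label = y, nthread = 1),
      nrounds = hp$nrounds, verbose = 0))
  structure(list(model_name = model_name, fit = fit, features = features,
                 target = target, hyperparameters = hp, seed = seed),
            class = "hrv_model")
}

#' @export
predict.hrv_model <- function(object, newdata, ...) {
  x <- newdata[, object$features, drop = FALSE]
  switch(object$model_name,
    linear        = unname(predict(object$fit, newdata = x)),
    decision_tree = unname(predict(object$fit, newdata = x)),
    random_forest = predict(object$fit, data = as.matrix(x),
                            num.threads = 1)$predictions,
    unname(predict(object$fit,
                   xgboost::xgb.DMatrix(as.matrix(x), nthread = 1))))
}

#' @export
print.hrv_model <- function(x, ...) {
  cat(sprintf("<hrv_model: %s> features: %s\n", x$model_name,
              paste(x$features, collapse = ", ")))
  invisible(x)
}

#' Fit a suite of regression models
#'
#' @param train Training tibble.
#' @param configs Either a character vector of model names or a list of
#'   lists with elements `model_name`, `hyperparameters`, `seed`.
#' @param seed Default seed for configs that do not carry one.
#' @inheritParams fit_regressor
#' @return A named list of `hrv_model` objects.
#' @export
train_regressors <- function(train, configs = MODEL_NAMES, seed = 42L,
                             features = NULL, target = "target") {
  if (is.character(configs)) {
    configs <- lapply(configs, function(nm) list(model_name = nm))
  }
  fits <- lapply(configs, function(cfg) {
    fit_regressor(train, cfg$model_name,
                  hyperparameters = cfg$hyperparameters %||% list(),
                  seed = cfg$seed %||% seed,
                  features = features, target = target)
  })
  stats::setNames(fits, vapply(configs, `[[`, character(1), "model_name"))
}

#' Regression metrics on an evaluation set
#'
#' `mse = mean((y - yhat)^2)`, `rmse = sqrt(mse)`, and
#' `r2 = 1 - mse / var_pop(y)` (population variance, so the identity
#' `rmse^2 = 1 - r2` holds exactly on a unit-variance target).
#'
#' @param model An `hrv_model` (or anything with a `predict` method over the
#'   model's features).
#' @param test Evaluation tibble.
#' @return One-row tibble: `model`, `r2`, `rmse`, `mse`, `n`.
#' @export
evaluate_regressor <- function(model, test) {
  y <- test[[model$target %||% "target"]]
  p <- predict(model, test)
  mse <- mean((y - p)^2)
  tibble::tibble(model = model$model_name %||% class(model)[1],
                 r2 = 1 - mse / mean((y - mean(y))^2),
                 rmse = sqrt(mse), mse = mse, n = length(y))
}

#' k-fold cross-validated mean squared error
#'
#' Shuffled, reproducible fold assignment; one model fit per fold; the mean
#' and variance of the per-fold MSEs summarize stability.
#'
#' @param data Full tibble to fold.
#' @param model_name,hyperparameters,seed,features,target As in
#'   [fit_regressor()].
#' @param k Number of folds (>= 2 and <= n rows).
#' @return One-row tibble `mse_mean`, `mse_var`, `k`, with the per-fold MSEs
#'   in attribute `"per_fold"`.
#' @export
cross_validate <- function(data, model_name = "random_forest",
                           hyperparameters = list(), k = 5L, seed = 42L,
                           features = NULL, target = "target") {
  n <- nrow(data)
  if (k < 2L) abort("k must be >= 2.", class = "hrvpipe_invalid_parameter")
  if (k > n) abort("k cannot exceed the number of rows.",
                   class = "hrvpipe_invalid_parameter")
  folds <- with_local_seed(seed, sample(rep_len(seq_len(k), n)))
  mses <- vapply(seq_len(k), function(f) {
    tr <- data[folds != f, , drop = FALSE]
    te <- data[folds == f, , drop = FALSE]
    m <- fit_regressor(tr, model_name, hyperparameters, seed = seed,
                       features = features, target = target)
    mean((te[[target]] - predict(m, te))^2)
  }, numeric(1))
  out <- tibble::tibble(mse_mean = mean(mses),
                        mse_var = if (k > 1) var(mses) else 0, k = k)
  attr(out, "per_fold") <- mses
  out
}

#' Thresholded classification metrics for probability targets
#'
#' Both the true and predicted typicality probabilities are binarized at the
#' same threshold with Positive = atypical = score below the threshold, then
#' accuracy, precision, recall and F1 are computed. When the truth contains
#' a single class, precision and recall are undefined and reported as 0 with
#' a warning.
#'
#' @param y_true_prob,y_pred_prob Vectors on the raw \[0, 1\] scale.
#' @param threshold Binarization threshold (default 0.5).
#' @return One-row tibble: `accuracy`, `precision`, `recall`, `f1`,
#'   `threshold_used`.
#' @export
classification_metrics <- function(y_true_prob, y_pred_prob, threshold = 0.5) {
  if (any(y_true_prob < 0 | y_true_prob > 1) ||
      any(y_pred_prob < 0 | y_pred_prob > 1)) {
    abort("Inputs must be probabilities in [0, 1].",
          class = "hrvpipe_invalid_parameter")
  }
  pos_t <- y_true_prob < threshold
  pos_p <- y_pred_prob < threshold
  tp <- sum(pos_t & pos_p); fp <- sum(!pos_t & pos_p)
  fn <- sum(pos_t & !pos_p); tn <- sum(!pos_t & !pos_p)
  if (all(pos_t) || all(!pos_t)) {
    warn("Truth contains a single class; precision/recall reported as 0.")
  }
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  tibble::tibble(accuracy = (tp + tn) / length(y_true_prob),
                 precision = precision, recall = recall, f1 = f1,
                 threshold_used = threshold)
}

#' Normalized feature importances of a tree-ensemble model
#'
#' Impurity-based importances normalized to sum to 1. Only defined for the
#' tree models (`decision_tree`, `random_forest`, `grad_boost_a`,
#' `grad_boost_b`).
#'
#' @param model An `hrv_model`.
#' @return Tibble `feature`, `importance`, sorted decreasing; features the
#'   model never used appear with importance 0.
#' @export
feature_importance <- function(model) {
  stopifnot(inherits(model, "hrv_model"))
  raw <- switch(model$model_name,
    random_forest = ranger::importance(model$fit),
    decision_tree = model$fit$variable.importance %||%
      stats::setNames(numeric(0), character(0)),
    grad_boost_a = ,
    grad_boost_b = {
      imp <- xgboost::xgb.importance(model = model$fit)
      stats::setNames(imp$Gain, imp$Feature)
    },
    abort("Feature importance is only defined for tree-based models.",
          class = "hrvpipe_invalid_parameter"))
  full <- stats::setNames(rep(0, length(model$features)), model$features)
  full[names(raw)] <- raw
  if (sum(full) > 0) full <- full / sum(full)
  tibble::tibble(feature = names(full), importance = unname(full)) |>
    dplyr::arrange(dplyr::desc(.data$importance))
}
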