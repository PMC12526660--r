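#' Benchmark the regression model suite on a processed table
#'
#' One call reproducing the full model comparison: stratified 80/20 split,
#' one fit per model, held-out R-squared / RMSE / MSE, k-fold
#' cross-validated MSE stability, thresholded classification metrics on the
#' raw probability scale (predictions are mapped back through the stored
#' target scaler and clamped to \[0, 1\]), random-forest feature
#' importances, and optionally a federated per-site variant evaluated on the
#' same held-out split.
#'
#' @param processed A [preprocess_features()] table (standardized target in
#'   `target`, raw probabilities in `target_raw`).
#' @param models Character vector of model names (see [fit_regressor()]).
#' @param seed Integer seed controlling the split, fits and folds.
#' @param test_frac Held-out fraction (default 0.2).
#' @param cv_k Cross-validation folds (default 5).
#' @param threshold Classification threshold on the raw scale (default 0.5).
#' @param rf_hyper Hyperparameters for the random forest (default: the tuned
#'   111 trees / depth 26).
#' @param federated Add a federated random-forest row when at least two
#'   sites are present (default `TRUE`).
#'
#' @return An object of class `hrv_benchmark`: list with `results` (one row
#'   per model: regression, CV and classification metrics), `importances`
#'   (random-forest), `models` (the fitted objects), `split`, and the
#'   settings. Use [tidy()], [glance()] and [autoplot()] on it.
#' @export
benchmark_models <- function(processed,
                             models = MODEL_NAMES,
                             seed = 42L, test_frac = 0.2, cv_k = 5L,
                             threshold = 0.5,
                             rf_hyper = list(num_trees = 111, max_depth = 26),
                             federated = TRUE) {
  assert_columns(processed, c("target", "target_raw"), "processed")
  report <- attr(processed, "report")
  split <- split_train_test(processed, test_frac = test_frac, seed = seed)
  features <- model_features(processed, "target")
  features <- setdiff(features, "record_seed")

  configs <- lapply(models, function(nm) {
    list(model_name = nm,
         hyperparameters = if (nm == "random_forest") rf_hyper else list())
  })
  fits <- train_regressors(split$train, configs, seed = seed,
                           features = features)

  to_raw <- function(p_std) {
    ts <- report$scaler[report$scaler$column == "target", ]
    raw <- if (nrow(ts) == 1L) p_std * ts$sd + ts$mean else p_std
    pmin(1, pmax(0, raw))
  }

  rows <- purrr::map_dfr(fits, function(m) {
    reg <- evaluate_regressor(m, split$test)
    cv <- cross_validate(split$train, m$model_name, m$hyperparameters,
                         k = cv_k, seed = seed, features = features)
    cls <- classification_metrics(split$test$target_raw,
                                  to_raw(predict(m, split$test)), threshold)
    dplyr::bind_cols(reg, dplyr::rename(cv, cv_mse_mean = "mse_mean",
                                        cv_mse_var = "mse_var")[, 1:2], cls)
  })

  if (federated && "site" %in% names(processed) &&
      length(unique(processed$site)) >= 2L) {
    fed <- federated_fit(split$train, "random_forest", rf_hyper,
                         seed = seed, features = features)
    fed$model_name <- "federated_rf"
    reg <- evaluate_regressor(fed, split$test)
    cls <- classification_metrics(split$test$target_raw,
                                  to_raw(predict(fed, split$test)), threshold)
    rows <- dplyr::bind_rows(rows, dplyr::bind_cols(
      reg, tibble::tibble(cv_mse_mean = NA_real_, cv_mse_var = NA_real_), cls))
    fits$federated_rf <- fed
  }

  structure(list(
    results = rows,
    importances = if ("random_forest" %in% names(fits))
      feature_importance(fits$random_forest),
    models = fits, split = split, seed = seed, threshold = threshold
  ), class = "hrv_benchmark")
}

#' @export
print.hrv_benchmark <- function(x, ...) {
  cat("<hrv_benchmark>\n")
  print.data.frame(as.data.frame(
    x$results[, c("model", "r2", "rmse", "cv_mse_mean", "accuracy", "f1")]),
    digits = 4, row.names = FALSE)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a model benchmark
#'
#' `tidy()` returns the per-model metric table; `glance()` returns a one-row
#' summary of the best model by held-out MSE.
#'
#' @param x An `hrv_benchmark`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.hrv_benchmark <- function(x, ...) x$results

#' @rdname tidy.hrv_benchmark
#' @export
glance.hrv_benchmark <- function(x, ...) {
  best <- x$results[which.min(x$results$mse), ]
  tibble::tibble(n_models = nrow(x$results), best_model = best$model,
                 best_r2 = best$r2, best_rmse = best$rmse,
                 best_accuracy = best$accuracy, seed = x$seed)
}

#' Tidy a fitted model
#'
#' Linear models yield their coefficients; tree models yield normalized
#' feature importances.
#'
#' @param x An `hrv_model`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.hrv_model <- function(x, ...) {
  if (x$model_name == "linear") {
    co <- stats::coef(x$fit)
    tibble::tibble(term = names(co), estimate = unname(co))
  } else {
    feature_importance(x)
  }
}
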