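#' Federated per-site model fitting
#'
#' Emulates a federation over recording sites: each site fits its own model
#' on its local rows only, and the federated prediction is the uniform
#' average of the per-site model predictions. Prediction-level aggregation
#' is used because tree ensembles have no averageable parameters; no raw
#' rows ever cross sites (each site model sees only its partition). Empty or
#' undersized partitions are skipped with a warning. A single-partition
#' federation is identical to centralized training.
#'
#' @param data Full tibble including the site column.
#' @param model_name,hyperparameters,seed,features,target As in
#'   [fit_regressor()].
#' @param site_col Name of the site column (default `"site"`).
#' @param min_rows Minimum rows a site needs to participate (default 10).
#' @return An object of class `hrv_federated` with the per-site models;
#'   `predict()` returns the averaged prediction.
#' @export
federated_fit <- function(data, model_name = "random_forest",
                          hyperparameters = list(), site_col = "site",
                          seed = 42L, features = NULL, target = "target",
                          min_rows = 10L) {
  assert_columns(data, site_col, "data")
  parts <- split(data, data[[site_col]])
  ok <- vapply(parts, nrow, integer(1)) >= min_rows
  if (any(!ok)) {
    warn(sprintf("Skipping %d site partition(s) with fewer than %d rows: %s",
                 sum(!ok), min_rows, paste(names(parts)[!ok], collapse = ", ")))
    parts <- parts[ok]
  }
  if (length(parts) == 0L) {
    abort("No site partition has enough rows.",
          class = "hrvpipe_insufficient_data")
  }
  features <- features %||% model_features(data, target)
  site_models <- lapply(parts, function(p) {
    fit_regressor(p, model_name, hyperparameters, seed = seed,
                  features = features, target = target)
  })
  structure(list(site_models = site_models, sites = names(parts),
                 model_name = model_name, features = features,
                 target = target),
            class = "hrv_federated")
}

#' @export
predict.hrv_federated <- function(object, newdata, ...) {
  preds <- vapply(object$site_models, predict, numeric(nrow(newdata)),
                  newdata = newdata)
  if (nrow(newdata) == 1L) return(mean(preds))
  rowMeans(preds)
}

#' @export
print.hrv_federated <- function(x, ...) {
  cat(sprintf("<hrv_federated: %s over %d sites (%s)>\n", x$model_name,
              length(x$sites), paste(x$sites, collapse = ", ")))
  invisible(x)
}
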