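#' Winsorize (cap) outliers in selected columns
#'
#' Clips each selected column to percentile caps (default the 5th and 95th,
#' linear-interpolation percentile definition) or, optionally, to Tukey
#' IQR fences (1.5 x IQR beyond the quartiles). Percentile capping is the
#' default because it is the operational statement of the preprocessing this
#' pipeline reproduces; the IQR mode is provided for comparison.
#'
#' @param data A data frame.
#' @param columns Character vector of columns to cap.
#' @param lower_pct,upper_pct Percentile caps (0 <= lower < upper <= 100).
#' @param method `"percentile"` (default) or `"iqr"`.
#'
#' @return `data` with the columns clipped; the per-column bounds are
#'   attached as attribute `"caps"` (a tibble: column, lower, upper).
#' @export
winsorize <- function(data, columns, lower_pct = 5, upper_pct = 95,
                      method = c("percentile", "iqr")) {
  method <- match.arg(method)
  assert_columns(data, columns, "data")
  if (!(lower_pct >= 0 && lower_pct < upper_pct && upper_pct <= 100)) {
    abort("Need 0 <= lower_pct < upper_pct <= 100.",
          class = "hrvpipe_invalid_parameter")
  }
  caps <- purrr::map_dfr(columns, function(col) {
    x <- data[[col]]
    if (length(x) == 0L || all(is.na(x))) {
      abort(sprintf("Column `%s` is empty.", col),
            class = "hrvpipe_invalid_parameter")
    }
    b <- if (method == "percentile") {
      quantile(x, c(lower_pct, upper_pct) / 100, type = 7, na.rm = TRUE)
    } else {
      q <- quantile(x, c(0.25, 0.75), type = 7, na.rm = TRUE)
      c(q[1] - 1.5 * diff(q), q[2] + 1.5 * diff(q))
    }
    tibble::tibble(column = col, lower = b[[1]], upper = b[[2]])
  })
  for (j in seq_len(nrow(caps))) {
    data[[caps$column[j]]] <- pmin(pmax(data[[caps$column[j]]], caps$lower[j]),
                                   caps$upper[j])
  }
  attr(data, "caps") <- caps
  data
}

#' Spearman rank correlation matrix
#'
#' Rank-based correlation (average ranks for ties) among the selected
#' columns, as used to screen features for multicollinearity. A constant
#' column has undefined correlation; it is recorded as 0 with a warning.
#'
#' @param data A data frame with at least 3 rows.
#' @param columns Columns to correlate; defaults to all numeric columns.
#' @return A symmetric correlation matrix with unit diagonal.
#' @export
spearman_matrix <- function(data, columns = NULL) {
  columns <- columns %||% names(data)[vapply(data, is.numeric, logical(1))]
  assert_columns(data, columns, "data")
  if (nrow(data) < 3L) {
    abort("At least 3 rows are required for a correlation matrix.",
          class = "hrvpipe_insufficient_data")
  }
  m <- suppressWarnings(
    cor(as.matrix(data[, columns, drop = FALSE]), method = "spearman"))
  if (anyNA(m)) {
    warn("Constant column(s): undefined Spearman correlations recorded as 0.")
    m[is.na(m)] <- 0
  }
  diag(m) <- 1
  m
}

merge_name <- function(a, b) {
  # the count/rate pair gets its conventional name; other merges are <a>_<b>
  if (setequal(c(a, b), c("r_peaks", "mean_hr"))) return("r_peak_mean_hr")
  paste(a, b, sep = "_")
}

#' Collapse collinear feature pairs into synthetic features
#'
#' For each feature pair whose absolute Spearman correlation exceeds the
#' threshold, both columns are replaced by a single synthetic column: the
#' mean of the two columns' z-scores (population-SD convention). Two
#' standardized unit-variance columns with correlation rho merge into a
#' column of variance `(1 + rho) / 2`, giving the synthetic feature the
#' bell-shaped, roughly unit-scale distribution expected downstream. With
#' the default feature set this merges `r_peaks` and `mean_hr` into
#' `r_peak_mean_hr`.
#'
#' @param data A data frame.
#' @param columns Candidate feature columns (default: all numeric).
#' @param threshold Absolute-correlation threshold (default 0.85).
#' @return `data` with merged columns; merge provenance (names, means, SDs,
#'   rho) attached as attribute `"merges"`.
#' @export
collapse_collinear <- function(data, columns = NULL, threshold = 0.85) {
  columns <- columns %||% names(data)[vapply(data, is.numeric, logical(1))]
  m <- spearman_matrix(data, columns)
  pairs <- which(abs(m) > threshold & upper.tri(m), arr.ind = TRUE)
  merges <- tibble::tibble(new = character(), a = character(), b = character(),
                           mean_a = numeric(), sd_a = numeric(),
                           mean_b = numeric(), sd_b = numeric(),
                           rho = numeric())
  if (nrow(pairs) > 0L) {
    ord <- order(-abs(m[pairs]))
    used <- character()
    for (p in ord) {
      a <- columns[pairs[p, 1]]; b <- columns[pairs[p, 2]]
      if (a %in% used || b %in% used) next
      zs <- function(x) (x - mean(x)) / pop_sd(x)
      new <- merge_name(a, b)
      data[[new]] <- (zs(data[[a]]) + zs(data[[b]])) / 2
      merges <- dplyr::add_row(merges, new = new, a = a, b = b,
                               mean_a = mean(data[[a]]), sd_a = pop_sd(data[[a]]),
                               mean_b = mean(data[[b]]), sd_b = pop_sd(data[[b]]),
                               rho = m[pairs[p, 1], pairs[p, 2]])
      data[[a]] <- NULL; data[[b]] <- NULL
      used <- c(used, a, b)
    }
  }
  attr(data, "merges") <- merges
  data
}

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Standardize columns to zero mean and unit variance
#'
#' Population-SD convention (divisor n), so a two-point column `c(0, 10)`
#' maps to `c(-1, 1)`. A previously fitted scaler (attribute `"scaler"` of an
#' earlier result, or its tibble) can be supplied to transform held-out rows
#' with training-set parameters.
#'
#' @param data A data frame.
#' @param columns Columns to scale.
#' @param scaler Optional tibble (column, mean, sd) from a previous fit.
#' @return `data` with scaled columns and attribute `"scaler"`.
#' @export
standardize <- function(data, columns, scaler = NULL) {
  assert_columns(data, columns, "data")
  if (is.null(scaler)) {
    scaler <- purrr::map_dfr(columns, function(col) {
      s <- pop_sd(data[[col]])
      if (!is.finite(s) || s == 0) {
        abort(sprintf("Column `%s` is constant and cannot be standardized.", col),
              class = "hrvpipe_invalid_parameter")
      }
      tibble::tibble(column = col, mean = mean(data[[col]]), sd = s)
    })
  }
  for (j in seq_len(nrow(scaler))) {
    col <- scaler$column[j]
    if (col %in% names(data)) {
      data[[col]] <- (data[[col]] - scaler$mean[j]) / scaler$sd[j]
    }
  }
  attr(data, "scaler") <- scaler
  data
}

#' Full preprocessing pass over a labeled feature table
#'
#' Applies the pipeline's preprocessing in its fixed order: percentile
#' winsorization of the physiological features, Spearman collinearity
#' screening with synthetic-feature construction, then standardization of
#' the features and (by default) the target. The raw probability target is
#' retained as `target_raw` for classification; the standardized copy in
#' `target` is the regression response, on which an R-squared of r
#' corresponds to an RMSE of sqrt(1 - r).
#'
#' @param labeled A [label_records()] output (needs `target` plus the
#'   feature columns).
#' @param feature_cols Feature columns entering the model matrix.
#' @param winsor_cols Columns to winsorize (defaults to the continuous
#'   physiological features; sex and the target are never capped).
#' @param lower_pct,upper_pct,outlier_method Passed to [winsorize()].
#' @param collinear_threshold Passed to [collapse_collinear()].
#' @param standardize_target Standardize the target too (default `TRUE`).
#'
#' @return The processed tibble, with a `report` attribute (list: `caps`,
#'   `merges`, `scaler`, plus the settings) that [apply_preprocess()] can
#'   replay on raw data. Access it with `preprocess_report()`.
#' @export
preprocess_features <- function(labeled,
                                feature_cols = c("age", "sex", "rmssd",
                                                 "mean_hr", "r_peaks"),
                                winsor_cols = c("age", "rmssd", "mean_hr",
                                                "r_peaks"),
                                lower_pct = 5, upper_pct = 95,
                                outlier_method = "percentile",
                                collinear_threshold = 0.85,
                                standardize_target = TRUE) {
  assert_columns(labeled, c(feature_cols, "target"), "labeled table")
  keep <- c("record_id", "site", feature_cols, "target")
  tbl <- labeled[, intersect(keep, names(labeled)), drop = FALSE]
  if (anyNA(tbl[, c(feature_cols, "target")])) {
    n0 <- nrow(tbl)
    tbl <- tidyr::drop_na(tbl, dplyr::all_of(c(feature_cols, "target")))
    warn(sprintf("Dropped %d row(s) with missing features.", n0 - nrow(tbl)))
  }
  tbl$target_raw <- tbl$target

  tbl <- winsorize(tbl, intersect(winsor_cols, feature_cols),
                   lower_pct, upper_pct, method = outlier_method)
  caps <- attr(tbl, "caps")
  tbl <- collapse_collinear(tbl, columns = feature_cols,
                            threshold = collinear_threshold)
  merges <- attr(tbl, "merges")
  final_feats <- c(setdiff(feature_cols, c(merges$a, merges$b)), merges$new)
  scale_cols <- c(final_feats, if (standardize_target) "target")
  tbl <- standardize(tbl, scale_cols)
  report <- list(caps = caps, merges = merges, scaler = attr(tbl, "scaler"),
                 feature_cols = feature_cols, final_features = final_feats,
                 winsor_cols = winsor_cols, lower_pct = lower_pct,
                 upper_pct = upper_pct, outlier_method = outlier_method,
                 collinear_threshold = collinear_threshold,
                 standardize_target = standardize_target)
  attr(tbl, "caps") <- NULL; attr(tbl, "merges") <- NULL
  attr(tbl, "scaler") <- NULL
  attr(tbl, "report") <- report
  tbl
}

#' @rdname preprocess_features
#' @param processed A [preprocess_features()] result.
#' @export
preprocess_report <- function(processed) attr(processed, "report")

#' Replay a stored preprocessing report on raw labeled data
#'
#' Applies the exact transformation recorded by [preprocess_features()]
#' (stored cap bounds, merge provenance and scaler parameters) to a raw
#' labeled table, e.g. held-out rows. Applying it to the original input
#' reproduces the processed table exactly.
#'
#' @param labeled Raw labeled tibble.
#' @param report A `preprocess_report()`.
#' @return The processed tibble.
#' @export
apply_preprocess <- function(labeled, report) {
  keep <- c("record_id", "site", report$feature_cols, "target")
  tbl <- labeled[, intersect(keep, names(labeled)), drop = FALSE]
  tbl <- tidyr::drop_na(tbl, dplyr::all_of(c(report$feature_cols, "target")))
  tbl$target_raw <- tbl$target
  for (j in seq_len(nrow(report$caps))) {
    col <- report$caps$column[j]
    tbl[[col]] <- pmin(pmax(tbl[[col]], report$caps$lower[j]),
                       report$caps$upper[j])
  }
  m <- report$merges
  for (j in seq_len(nrow(m))) {
    tbl[[m$new[j]]] <- ((tbl[[m$a[j]]] - m$mean_a[j]) / m$sd_a[j] +
                        (tbl[[m$b[j]]] - m$mean_b[j]) / m$sd_b[j]) / 2
    tbl[[m$a[j]]] <- NULL; tbl[[m$b[j]]] <- NULL
  }
  tbl <- standardize(tbl, report$scaler$column, scaler = report$scaler)
  attr(tbl, "scaler") <- NULL
  attr(tbl, "report") <- report
  tbl
}
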