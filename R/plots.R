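#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_line geom_point
#'   geom_errorbar geom_ribbon labs theme_minimal
#' @export
ggplot2::autoplot

#' Plot a model benchmark
#'
#' Bar chart of held-out MSE per model with cross-validation SD whiskers
#' (where available), mirroring the customary model-comparison figure.
#'
#' @param object An `hrv_benchmark`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hrv_benchmark <- function(object, ...) {
  d <- dplyr::mutate(object$results,
                     cv_sd = sqrt(pmax(.data$cv_mse_var, 0)),
                     model = stats::reorder(.data$model, .data$mse))
  ggplot(d, aes(x = .data$model, y = .data$mse)) +
    geom_col(fill = "steelblue") +
    geom_errorbar(aes(ymin = pmax(0, .data$mse - .data$cv_sd),
                      ymax = .data$mse + .data$cv_sd),
                  width = 0.2, na.rm = TRUE) +
    labs(x = NULL, y = "Held-out MSE (standardized target)",
         title = "Model comparison",
         subtitle = "Whiskers: cross-validated MSE standard deviation") +
    theme_minimal()
}

#' Plot a hyperparameter optimization trace
#'
#' Per-evaluation cross-validated MSE and the running best, showing the
#' convergence of the Gaussian-process search.
#'
#' @param object An `hrv_opt_trace` from [optimize_rf()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hrv_opt_trace <- function(object, ...) {
  ggplot(object$trace, aes(x = .data$iter)) +
    geom_point(aes(y = .data$cv_mse), colour = "grey40") +
    geom_line(aes(y = .data$best_so_far), colour = "firebrick") +
    labs(x = "Evaluation", y = "Cross-validated MSE",
         title = "Random-forest hyperparameter optimization",
         subtitle = "Points: evaluations; line: best so far") +
    theme_minimal()
}

#' Plot the normative reference bands
#'
#' Total range, median range and fitted mode per age band.
#'
#' @param object An `hrv_reference` from [reference_bands()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hrv_reference <- function(object, ...) {
  d <- dplyr::mutate(tibble::as_tibble(object),
                     age_mid = (.data$age_low + .data$age_high) / 2)
  ggplot(d, aes(x = .data$age_mid)) +
    geom_ribbon(aes(ymin = 1000 * .data$range_low_s,
                    ymax = 1000 * .data$range_high_s),
                fill = "steelblue", alpha = 0.25) +
    geom_ribbon(aes(ymin = 1000 * .data$median_low_s,
                    ymax = 1000 * .data$median_high_s),
                fill = "steelblue", alpha = 0.6) +
    geom_line(aes(y = .data$mu_ms)) +
    labs(x = "Age (years)", y = "RMSSD (ms)",
         title = "Normative RMSSD reference bands",
         subtitle = "Light: total range; dark: median range; line: fitted mode") +
    theme_minimal()
}
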