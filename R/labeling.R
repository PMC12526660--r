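#' Age-stratified normative RMSSD reference bands
#'
#' Builds the per-decade reference table that drives the typicality score:
#' each band (20-29 ... 80-89 years) carries a normative median range and a
#' total range for RMSSD (seconds), plus the parameters of a fitted
#' asymmetric normal (see [fit_band_normal()]).
#'
#' With `source = "printed_defaults"` the 20-29 band (median 0.0041-0.0048 s,
#' total 0.0013-0.0161 s) and the 60-69 band (median 0.00204-0.00207 s,
#' total 0.0005-0.0104 s) anchor the table and the remaining decade bands are
#' linearly interpolated/extrapolated in median midpoint, median width and
#' range endpoints. The interpolated median width is clamped at zero for the
#' oldest bands, where the linear trend would cross it. The published 60-69
#' median upper bound appears with a misplaced decimal (0.000207 s, which
#' would invert the bounds) and is read as 0.00207 s; a note is emitted when
#' the defaults are used. Note that these normative ranges sit in the
#' few-millisecond regime, well below typical cohort RMSSD values, so most
#' realistic records score through the out-of-range branch; this is surfaced
#' rather than altered because the reference table is data, not code.
#'
#' Alternatively `source` may be a path to a CSV with columns `age_low`,
#' `age_high`, `median_low_s`, `median_high_s`, `range_low_s`,
#' `range_high_s`; bands must be contiguous, non-overlapping decades (or any
#' contiguous partition).
#'
#' @param source `"printed_defaults"` or a CSV path.
#' @param coverage Central probability mass the total range must span when
#'   fitting the normal (default 0.96).
#' @param quiet Suppress the informational notes.
#'
#' @return A tibble of class `hrv_reference` with one row per band and
#'   columns `age_low`, `age_high`, `median_low_s`, `median_high_s`,
#'   `range_low_s`, `range_high_s`, `mu_ms`, `sigma_low_ms`, `sigma_high_ms`,
#'   `sigma_ms`; attribute `coverage`.
#' @export
reference_bands <- function(source = "printed_defaults", coverage = 0.96,
                            quiet = FALSE) {
  assert_scalar_number(coverage, "coverage",
                       lower = .Machine$double.eps, upper = 1 - 1e-12)
  if (identical(source, "printed_defaults")) {
    if (!quiet) {
      rlang::inform(c(
        "Using printed normative defaults.",
        i = "60-69 median upper bound read as 0.00207 s (published value 0.000207 s inverts the bounds).",
        i = "Normative ranges are in the low-millisecond regime; most realistic RMSSD values fall out of range."
      ))
    }
    k <- 0:6
    lerp <- function(a20, a60) a20 + (a60 - a20) / 4 * k
    mid <- lerp((0.0041 + 0.0048) / 2, (0.00204 + 0.00207) / 2)
    wid <- pmax(0, lerp(0.0048 - 0.0041, 0.00207 - 0.00204))
    bands <- tibble::tibble(
      age_low = 20 + 10 * k, age_high = 29 + 10 * k,
      median_low_s = mid - wid / 2, median_high_s = mid + wid / 2,
      range_low_s = lerp(0.0013, 0.0005), range_high_s = lerp(0.0161, 0.0104)
    )
  } else {
    bands <- readr::read_csv(source, show_col_types = FALSE)
    assert_columns(bands, c("age_low", "age_high", "median_low_s",
                            "median_high_s", "range_low_s", "range_high_s"),
                   "reference band file")
    bands <- dplyr::arrange(bands, .data$age_low)
  }
  validate_bands(bands)
  fitted <- purrr::pmap_dfr(
    bands[, c("median_low_s", "median_high_s", "range_low_s", "range_high_s")],
    function(median_low_s, median_high_s, range_low_s, range_high_s) {
      fit_band_normal(median_low_s, median_high_s, range_low_s, range_high_s,
                      coverage)
    })
  out <- dplyr::bind_cols(bands, fitted)
  class(out) <- c("hrv_reference", class(out))
  attr(out, "coverage") <- coverage
  out
}

validate_bands <- function(bands) {
  with(bands, {
    if (any(range_low_s >= median_low_s) || any(median_low_s > median_high_s) ||
        any(median_high_s >= range_high_s)) {
      abort("Each band needs range_low < median_low <= median_high < range_high.",
            class = "hrvpipe_invalid_reference")
    }
  })
  if (nrow(bands) > 1L) {
    lo <- bands$age_low[-1]; hi <- bands$age_high[-nrow(bands)]
    if (any(lo != hi + 1)) {
      abort("Reference bands must partition the age span without overlap or gaps.",
            class = "hrvpipe_invalid_reference")
    }
  }
  invisible(bands)
}

#' Fit an asymmetric normal to a normative band
#'
#' Converts a band's printed median range and total range (seconds) into the
#' parameters of a two-piece (split) normal on the millisecond scale: the
#' mode `mu_ms` is the midpoint of the median range, and each side's sigma is
#' chosen so that the total range spans the central `coverage` mass --
#' `sigma_low = (mu - range_low)/q`, `sigma_high = (range_high - mu)/q` with
#' `q = qnorm((1 + coverage)/2)`. Under a two-piece normal the probability of
#' falling inside the total range is then exactly `coverage` for any band,
#' while the distribution stays centered on the published medians. The
#' reported `sigma_ms` is the mean of the two side sigmas, which equals the
#' symmetric-fit value `range width / (2 q)`.
#'
#' @param median_low_s,median_high_s Median range bounds (seconds).
#' @param range_low_s,range_high_s Total range bounds (seconds).
#' @param coverage Central mass the total range spans (default 0.96).
#'
#' @return A one-row tibble: `mu_ms`, `sigma_low_ms`, `sigma_high_ms`,
#'   `sigma_ms` (milliseconds).
#' @examples
#' fit_band_normal(0.0041, 0.0048, 0.0013, 0.0161) # mu 4.45, sigma ~3.603
#' @export
fit_band_normal <- function(median_low_s, median_high_s, range_low_s,
                            range_high_s, coverage = 0.96) {
  assert_scalar_number(coverage, "coverage",
                       lower = .Machine$double.eps, upper = 1 - 1e-12)
  if (range_high_s - range_low_s <= 0) {
    abort("Degenerate band: total range has zero width.",
          class = "hrvpipe_invalid_reference")
  }
  q <- qnorm((1 + coverage) / 2)
  mu <- 1000 * (median_low_s + median_high_s) / 2
  sl <- (mu - 1000 * range_low_s) / q
  sh <- (1000 * range_high_s - mu) / q
  if (sl <= 0 || sh <= 0) {
    abort("Band medians must lie strictly inside the total range.",
          class = "hrvpipe_invalid_reference")
  }
  tibble::tibble(mu_ms = mu, sigma_low_ms = sl, sigma_high_ms = sh,
                 sigma_ms = (sl + sh) / 2)
}

band_for_age <- function(refs, age) {
  idx <- findInterval(floor(age), refs$age_low)
  idx[floor(age) > refs$age_high[pmax(idx, 1L)] | idx == 0L] <- NA_integer_
  idx
}

#' Age-adjusted RMSSD typicality score
#'
#' The probabilistic target of the pipeline: how typical a record's RMSSD is
#' for its age band, on \[0, 1\]. With the fitted band parameters
#' (see [fit_band_normal()]), the standardized score is
#' `z = (rmssd - mu)/sigma_side` using the sigma of the side of the mode the
#' value falls on. Inside the band's total range the score is a cumulative
#' normal probability: in the default `two_sided` mode,
#' `2 * min(pnorm(z), 1 - pnorm(z))` -- 1 at the mode, falling symmetrically
#' in z, and equal to `2 * (1 - (1 + coverage)/2)` (0.04 at the default 96%
#' coverage) exactly at either range boundary. The `literal_cdf` mode returns
#' the raw `pnorm(z)` instead (monotone across the range, so low RMSSD scores
#' near 0 and high RMSSD near 1). Outside the range the score decays
#' exponentially with the distance `d` beyond the nearer boundary:
#' `score(boundary) * exp(-decay_rate_per_sigma * d / sigma_side)`, anchored
#' at the within-range boundary score so the two branches meet continuously.
#' Scores are clamped to \[0, 1\].
#'
#' @param rmssd_ms RMSSD values in milliseconds (vectorized, >= 0).
#' @param band A single fitted band: one row of [reference_bands()].
#' @param mode `"two_sided"` (default) or `"literal_cdf"`.
#' @param decay_rate_per_sigma Out-of-range decay rate per side-sigma of
#'   exceedance (> 0, default 1).
#'
#' @return A tibble with one row per input: `z`, `in_range`,
#'   `boundary_distance_ms` (0 when in range), `score`.
#' @export
typicality_score <- function(rmssd_ms, band, mode = c("two_sided", "literal_cdf"),
                             decay_rate_per_sigma = 1) {
  mode <- match.arg(mode)
  assert_scalar_number(decay_rate_per_sigma, "decay_rate_per_sigma",
                       lower = .Machine$double.eps)
  if (!all(c("mu_ms", "sigma_low_ms", "sigma_high_ms") %in% names(band)) ||
      nrow(band) != 1L || !is.finite(band$sigma_low_ms)) {
    abort("`band` must be a single fitted reference band.",
          class = "hrvpipe_invalid_reference")
  }
  if (any(rmssd_ms < 0)) {
    abort("RMSSD must be non-negative.", class = "hrvpipe_invalid_parameter")
  }
  rl <- 1000 * band$range_low_s; rh <- 1000 * band$range_high_s
  s_side <- ifelse(rmssd_ms < band$mu_ms, band$sigma_low_ms, band$sigma_high_ms)
  z <- (rmssd_ms - band$mu_ms) / s_side
  in_range <- rmssd_ms >= rl & rmssd_ms <= rh
  d <- pmax(0, rl - rmssd_ms, rmssd_ms - rh)

  inner <- switch(mode,
    two_sided   = 2 * pmin(pnorm(z), 1 - pnorm(z)),
    literal_cdf = pnorm(z))
  # boundary z is -q (lower) / +q (upper) by construction of the fit
  q <- (rh - band$mu_ms) / band$sigma_high_ms
  s_b <- switch(mode,
    two_sided   = rep(2 * (1 - pnorm(q)), length(rmssd_ms)),
    literal_cdf = ifelse(rmssd_ms < band$mu_ms, pnorm(-q), pnorm(q)))
  outer <- s_b * exp(-decay_rate_per_sigma * d / s_side)

  score <- pmin(1, pmax(0, ifelse(in_range, inner, outer)))
  tibble::tibble(z = z, in_range = in_range, boundary_distance_ms = d,
                 score = score)
}

#' Label a feature table with typicality targets
#'
#' Scores every record's RMSSD against its age band and appends the
#' probability target plus the score breakdown. Rows whose age falls outside
#' the span of the reference table are excluded with a warning.
#'
#' @param features Feature tibble with at least `age` and `rmssd` (seconds).
#' @param refs A [reference_bands()] table.
#' @param mode,decay_rate_per_sigma Passed to [typicality_score()].
#' @param quiet Suppress the per-band summary message.
#'
#' @return `features` (minus excluded rows) with columns `target` (in
#'   \[0, 1\]), `z`, `in_range` and `boundary_distance_ms` appended.
#' @export
label_records <- function(features, refs, mode = "two_sided",
                          decay_rate_per_sigma = 1, quiet = TRUE) {
  assert_columns(features, c("age", "rmssd"), "features")
  idx <- band_for_age(refs, features$age)
  if (anyNA(idx)) {
    warn(sprintf("Excluding %d record(s) with age outside the reference span (%g-%g).",
                 sum(is.na(idx)), min(refs$age_low), max(refs$age_high)))
    features <- features[!is.na(idx), , drop = FALSE]
    idx <- idx[!is.na(idx)]
  }
  if (nrow(features) == 0L) {
    abort("No record has an age inside the reference span.",
          class = "hrvpipe_invalid_reference")
  }
  parts <- lapply(split(seq_len(nrow(features)), idx), function(rows) {
    b <- refs[idx[rows[1]], ]
    sb <- typicality_score(features$rmssd[rows] * 1000, b, mode = mode,
                           decay_rate_per_sigma = decay_rate_per_sigma)
    dplyr::bind_cols(features[rows, , drop = FALSE],
                     dplyr::rename(sb, target = "score"))
  })
  out <- dplyr::arrange(dplyr::bind_rows(parts), dplyr::across("record_id"))
  if (!quiet) {
    tab <- table(factor(idx, levels = seq_len(nrow(refs))))
    rlang::inform(paste0("Labeled ", nrow(out), " records; per-band counts: ",
                         paste(tab, collapse = "/"),
                         "; in-range fraction ", round(mean(out$in_range), 3)))
  }
  out
}

#' Sample RMSSD values from a fitted band distribution
#'
#' Draws from the band's two-piece normal: a side is chosen with probability
#' proportional to its sigma (the continuous-density weighting), then a
#' half-normal deviate on that side of the mode. The probability that a draw
#' lands inside the band's total range equals the fitted `coverage` exactly.
#'
#' @param n Number of draws.
#' @param band One fitted row of [reference_bands()].
#' @param seed Optional integer seed (local to this call).
#' @return Numeric vector of RMSSD draws in milliseconds (may be negative in
#'   the extreme lower tail; callers modeling physical RMSSD should truncate).
#' @export
sample_band_rmssd <- function(n, band, seed = NULL) {
  stopifnot(nrow(band) == 1L, n >= 1)
  with_local_seed(seed, {
    w_low <- band$sigma_low_ms / (band$sigma_low_ms + band$sigma_high_ms)
    low <- runif(n) < w_low
    dev <- abs(rnorm(n))
    band$mu_ms + ifelse(low, -dev * band$sigma_low_ms, dev * band$sigma_high_ms)
  })
}
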