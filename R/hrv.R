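#' Successive R-to-R intervals from R-peak times
#'
#' Converts a strictly increasing vector of R-peak times (seconds) into the
#' series of successive R-to-R (RR) intervals in milliseconds, the raw
#' material for all time-domain heart rate variability (HRV) indices.
#'
#' @param times_s Numeric vector of R-peak times in seconds, strictly
#'   increasing, length at least 2.
#'
#' @return Numeric vector of RR intervals in milliseconds
#'   (`length(times_s) - 1`).
#' @examples
#' rr_from_peaks(c(0, 0.8, 1.7)) # 800 900
#' @export
rr_from_peaks <- function(times_s) {
  if (!is.numeric(times_s) || length(times_s) < 2L) {
    abort("At least two R-peak times are required to form RR intervals.",
          class = "hrvpipe_insufficient_data")
  }
  d <- diff(times_s)
  if (any(d <= 0)) {
    abort("R-peak times must be strictly increasing.",
          class = "hrvpipe_invalid_parameter")
  }
  d * 1000
}

#' Root mean square of successive differences (RMSSD)
#'
#' The canonical short-term HRV index: the square root of the mean of the
#' squared differences between successive RR intervals,
#' \eqn{\sqrt{\mathrm{mean}((RR_{i+1}-RR_i)^2)}}. RMSSD reflects beat-to-beat
#' (parasympathetically driven) variability and is reported here in the same
#' unit as its input.
#'
#' @param rr_ms Numeric vector of successive RR intervals in milliseconds,
#'   all positive, length at least 2.
#'
#' @return RMSSD in milliseconds (scalar, non-negative).
#' @examples
#' rmssd(c(800, 810, 790, 805)) # ~15.546
#' @export
rmssd <- function(rr_ms) {
  if (!is.numeric(rr_ms) || length(rr_ms) < 2L) {
    abort("At least two RR intervals are required for RMSSD.",
          class = "hrvpipe_insufficient_data")
  }
  if (any(rr_ms <= 0)) {
    abort("RR intervals must be positive.", class = "hrvpipe_invalid_parameter")
  }
  sqrt(mean(diff(rr_ms)^2))
}

#' Mean heart rate from RR intervals
#'
#' @param rr_ms Numeric vector of RR intervals in milliseconds (non-empty,
#'   positive).
#' @return Mean heart rate in beats per minute: `60000 / mean(rr_ms)`.
#' @examples
#' mean_heart_rate(rep(1200, 10)) # 50 bpm
#' @export
mean_heart_rate <- function(rr_ms) {
  if (!is.numeric(rr_ms) || length(rr_ms) < 1L) {
    abort("At least one RR interval is required for mean heart rate.",
          class = "hrvpipe_insufficient_data")
  }
  if (any(rr_ms <= 0)) {
    abort("RR intervals must be positive.", class = "hrvpipe_invalid_parameter")
  }
  60000 / mean(rr_ms)
}

#' HRV features for a single ECG record
#'
#' Runs R-peak detection on a raw waveform and derives the three per-record
#' physiological features used throughout the pipeline: RMSSD (stored in
#' seconds in feature tables, matching the cohort-level convention), mean
#' heart rate (bpm) and the R-peak count. Records with fewer than three
#' detected peaks are flagged rather than erroring, so batch runs can skip
#' and log them.
#'
#' @param signal Numeric waveform in millivolts.
#' @param fs Sampling rate in Hz.
#'
#' @return A one-row tibble with columns `rmssd` (seconds), `mean_hr` (bpm),
#'   `r_peaks` (count) and `flagged` (logical; `TRUE` when the record could
#'   not be featurized, in which case the numeric columns are `NA`).
#' @seealso [detect_rpeaks()], [compute_features()]
#' @export
features_from_record <- function(signal, fs) {
  peaks <- detect_rpeaks(signal, fs)
  if (nrow(peaks) < 3L) {
    warn(sprintf("Record flagged: only %d R-peak(s) detected (need >= 3).",
                 nrow(peaks)))
    return(tibble::tibble(rmssd = NA_real_, mean_hr = NA_real_,
                          r_peaks = nrow(peaks), flagged = TRUE))
  }
  rr <- rr_from_peaks(peaks$time_s)
  tibble::tibble(
    rmssd   = rmssd(rr) / 1000,
    mean_hr = mean_heart_rate(rr),
    r_peaks = nrow(peaks),
    flagged = FALSE
  )
}

#' HRV feature table for a synthetic cohort
#'
#' Builds the per-record feature table (one row per record: demographics plus
#' RMSSD, mean heart rate, R-peak count) for a cohort produced by
#' [generate_cohort()].
#'
#' By default features are computed from the generator's ground-truth R-peak
#' times. With `from = "detector"` each record's waveform is synthesized and
#' passed through the full [detect_rpeaks()] path instead, which is the
#' configuration used to validate detector fidelity.
#'
#' @param cohort A cohort tibble from [generate_cohort()].
#' @param from `"truth"` (default) to featurize ground-truth R-peak times,
#'   `"detector"` to synthesize waveforms and re-detect peaks.
#' @param qrs_amplitude_mv,noise_sd_mv Waveform synthesis settings, used only
#'   when `from = "detector"`.
#'
#' @return A tibble with columns `record_id`, `age`, `sex`, `site`, `rmssd`
#'   (seconds), `mean_hr` (bpm), `r_peaks`, `flagged`. Flagged rows (never
#'   produced by the truth path) carry `NA` features.
#' @export
compute_features <- function(cohort, from = c("truth", "detector"),
                             qrs_amplitude_mv = 1, noise_sd_mv = 0) {
  from <- match.arg(from)
  assert_columns(cohort, c("record_id", "age", "sex", "site", "r_times_s"),
                 "cohort")
  fs <- attr(cohort, "config")$fs %||% 500
  feats <- purrr::map(seq_len(nrow(cohort)), function(i) {
    truth_times <- cohort$r_times_s[[i]]
    if (from == "truth") {
      if (length(truth_times) < 3L) {
        return(tibble::tibble(rmssd = NA_real_, mean_hr = NA_real_,
                              r_peaks = length(truth_times), flagged = TRUE))
      }
      rr <- rr_from_peaks(truth_times)
      tibble::tibble(rmssd = rmssd(rr) / 1000, mean_hr = mean_heart_rate(rr),
                     r_peaks = length(truth_times), flagged = FALSE)
    } else {
      wf <- synthesize_ecg(cohort$rr_ms[[i]], fs = fs,
                           qrs_amplitude_mv = qrs_amplitude_mv,
                           noise_sd_mv = noise_sd_mv,
                           seed = derive_seed(cohort$record_seed[i], "ecg"))
      features_from_record(wf$signal, fs)
    }
  })
  meta <- dplyr::mutate(
    dplyr::select(cohort, "record_id", "age", "sex", "site"),
    sex = as.numeric(.data$sex == "female")  # male -> 0, female -> 1
  )
  dplyr::bind_cols(meta, dplyr::bind_rows(feats))
}
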