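# WFDB support is a minimal format-16 implementation (.hea header + .dat of
# little-endian 16-bit samples, gain in adu/mV), sufficient to round-trip the
# records this package produces and to read equivalent single-lead files.
WFDB_GAIN <- 200L

#' Write a single ECG record
#'
#' @param record A list with `record_id`, `signal` (mV), `fs`, and optional
#'   `age`, `sex` (`"male"`/`"female"`), `site_id`.
#' @param dir Output directory (created if needed).
#' @param format `"wfdb"` (a `.hea`/`.dat` pair) or `"csv"` (an
#'   `<id>.csv` with one `amplitude_mv` column plus an `<id>.meta.csv`
#'   sidecar).
#' @return The path of the header/CSV file, invisibly.
#' @export
write_ecg_record <- function(record, dir, format = c("wfdb", "csv")) {
  format <- match.arg(format)
  stopifnot(is.list(record), !is.null(record$record_id),
            is.numeric(record$signal), length(record$signal) > 0)
  assert_scalar_number(record$fs, "fs", lower = .Machine$double.eps)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  id <- record$record_id
  if (format == "wfdb") {
    hea <- file.path(dir, paste0(id, ".hea"))
    dat <- file.path(dir, paste0(id, ".dat"))
    writeLines(c(
      sprintf("%s 1 %s %d", id, format(record$fs), length(record$signal)),
      sprintf("%s.dat 16 %d/mV 16 0 0 0 0 ECG", id, WFDB_GAIN),
      sprintf("# age: %s", record$age %||% "NA"),
      sprintf("# sex: %s", record$sex %||% "NA"),
      sprintf("# site: %s", record$site_id %||% "NA")
    ), hea)
    adu <- as.integer(round(record$signal * WFDB_GAIN))
    con <- file(dat, "wb"); on.exit(close(con))
    writeBin(adu, con, size = 2L, endian = "little")
    invisible(hea)
  } else {
    csv <- file.path(dir, paste0(id, ".csv"))
    readr::write_csv(tibble::tibble(amplitude_mv = record$signal), csv)
    readr::write_csv(tibble::tibble(
      record_id = id, fs = record$fs,
      age = record$age %||% NA_real_, sex = record$sex %||% NA_character_,
      site_id = record$site_id %||% NA_character_
    ), file.path(dir, paste0(id, ".meta.csv")))
    invisible(csv)
  }
}

#' Read a single ECG record
#'
#' Reads a record written by [write_ecg_record()] (or an equivalent
#' single-lead WFDB format-16 pair). Records missing age or sex are returned
#' with `flagged = TRUE` and a warning so downstream batch stages can exclude
#' them.
#'
#' @param path Path to the `.hea` file, the record `.csv`, or the record stem.
#' @param format `"auto"` (by extension), `"wfdb"` or `"csv"`.
#' @return A list: `record_id`, `signal` (mV), `fs`, `age`, `sex`,
#'   `site_id`, `flagged`.
#' @export
read_ecg_record <- function(path, format = c("auto", "wfdb", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path)) "csv" else "wfdb"
  }
  if (format == "wfdb") {
    hea <- if (grepl("\\.hea$", path)) path else paste0(path, ".hea")
    if (!file.exists(hea)) {
      abort(sprintf("Header file not found: %s", hea), class = "hrvpipe_format_error")
    }
    lines <- readLines(hea)
    top <- strsplit(trimws(lines[1]), "\\s+")[[1]]
    if (length(top) < 4L) {
      abort("Malformed WFDB header: record line needs <id> <nsig> <fs> <nsamp>.",
            class = "hrvpipe_format_error")
    }
    fs <- as.numeric(top[3]); nsamp <- as.integer(top[4])
    if (!is.finite(fs) || fs <= 0) {
      abort("Malformed WFDB header: non-numeric sampling rate.",
            class = "hrvpipe_format_error")
    }
    sig_line <- strsplit(trimws(lines[2]), "\\s+")[[1]]
    gain <- suppressWarnings(as.numeric(sub("/.*$", "", sig_line[3])))
    if (!is.finite(gain) || gain <= 0) gain <- WFDB_GAIN
    meta_of <- function(key) {
      m <- grep(sprintf("^#\\s*%s:", key), lines, value = TRUE)
      if (length(m) == 0L) return(NA_character_)
      trimws(sub(sprintf("^#\\s*%s:", key), "", m[1]))
    }
    dat <- file.path(dirname(hea), sub("\\s.*$", "", sig_line[1]))
    if (!file.exists(dat)) {
      abort(sprintf("Signal file not found: %s", dat), class = "hrvpipe_format_error")
    }
    con <- file(dat, "rb"); on.exit(close(con))
    adu <- readBin(con, "integer", n = nsamp, size = 2L, endian = "little")
    rec <- list(record_id = top[1], signal = adu / gain, fs = fs,
                age = suppressWarnings(as.numeric(meta_of("age"))),
                sex = meta_of("sex"), site_id = meta_of("site"))
  } else {
    if (!file.exists(path)) {
      abort(sprintf("File not found: %s", path), class = "hrvpipe_format_error")
    }
    raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"))
    if (!"amplitude_mv" %in% names(raw)) {
      abort("Record CSV must have an `amplitude_mv` column.",
            class = "hrvpipe_format_error")
    }
    vals <- suppressWarnings(as.numeric(raw$amplitude_mv))
    bad <- which(is.na(vals) & !is.na(raw$amplitude_mv))
    if (length(bad) > 0L) {
      abort(sprintf("Non-numeric sample in `amplitude_mv` at line %d of %s.",
                    bad[1] + 1L, path),
            class = "hrvpipe_format_error")
    }
    meta_path <- sub("\\.csv$", ".meta.csv", path)
    meta <- if (file.exists(meta_path)) {
      readr::read_csv(meta_path, show_col_types = FALSE)
    } else tibble::tibble()
    rec <- list(
      record_id = meta$record_id %||% sub("\\.csv$", "", basename(path)),
      signal = vals,
      fs = meta$fs %||% NA_real_,
      age = suppressWarnings(as.numeric(meta$age %||% NA)),
      sex = as.character(meta$sex %||% NA), site_id = as.character(meta$site_id %||% NA)
    )
    if (!is.finite(rec$fs)) {
      abort(sprintf("Sampling rate missing for %s (no sidecar %s).",
                    path, basename(meta_path)),
            class = "hrvpipe_format_error")
    }
  }
  rec$sex[rec$sex %in% c("NA", "")] <- NA_character_
  rec$flagged <- !is.finite(rec$age) || is.na(rec$sex)
  if (rec$flagged) {
    warn(sprintf("Record %s is missing age or sex; flagged for exclusion.",
                 rec$record_id))
  }
  rec
}

#' Write and read per-record feature tables
#'
#' Feature tables are plain UTF-8 CSVs with a header row, `.` decimal
#' separator and a deterministic column order (the canonical columns
#' `record_id`, `age`, `sex`, `rmssd`, `mean_hr`, `r_peaks`, `target` first,
#' then any extras in their existing order).
#'
#' @param table A feature tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly (`write_feature_table`); a tibble
#'   (`read_feature_table`).
#' @export
write_feature_table <- function(table, path) {
  canonical <- c("record_id", "age", "sex", "rmssd", "mean_hr", "r_peaks",
                 "target")
  ord <- c(intersect(canonical, names(table)),
           setdiff(names(table), canonical))
  readr::write_csv(table[, ord, drop = FALSE], path)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' Export a synthetic cohort to disk
#'
#' Writes one waveform file per record (WFDB pair or CSV; synthesized on the
#' fly from the record's RR series), a cohort metadata CSV
#' (`cohort_meta.csv`: record_id, age, sex, site) and a ground-truth CSV of
#' R-peak times in seconds (`ground_truth.csv`).
#'
#' @param cohort A [generate_cohort()] tibble.
#' @param dir Output directory.
#' @param format `"csv"` or `"wfdb"`.
#' @param qrs_amplitude_mv,noise_sd_mv Waveform synthesis settings.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, format = c("csv", "wfdb"),
                         qrs_amplitude_mv = 1, noise_sd_mv = 0) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fs <- attr(cohort, "config")$fs %||% 500
  for (i in seq_len(nrow(cohort))) {
    wf <- synthesize_ecg(cohort$rr_ms[[i]], fs = fs,
                         qrs_amplitude_mv = qrs_amplitude_mv,
                         noise_sd_mv = noise_sd_mv,
                         seed = derive_seed(cohort$record_seed[i], "ecg"))
    write_ecg_record(list(record_id = cohort$record_id[i], signal = wf$signal,
                          fs = fs, age = cohort$age[i], sex = cohort$sex[i],
                          site_id = cohort$site[i]),
                     dir, format = format)
  }
  readr::write_csv(
    dplyr::select(tibble::as_tibble(cohort), "record_id", "age", "sex", "site"),
    file.path(dir, "cohort_meta.csv"))
  truth <- tidyr::unnest(
    dplyr::select(tibble::as_tibble(cohort), "record_id", "r_times_s"),
    "r_times_s")
  readr::write_csv(truth, file.path(dir, "ground_truth.csv"))
  invisible(dir)
}
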