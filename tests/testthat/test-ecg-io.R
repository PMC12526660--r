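quantized_record <- function() {
  # amplitudes on the WFDB adu grid (1/200 mV) so round-trips are exact
  list(record_id = "rec_a", signal = round(sin(seq_len(2000) / 20) * 200) / 200,
       fs = 500, age = 63, sex = "female", site_id = "site_2")
}

test_that("WFDB records round-trip samples, rate and metadata", {
  rec <- quantized_record()
  dir <- withr::local_tempdir()
  write_ecg_record(rec, dir, format = "wfdb")
  back <- read_ecg_record(file.path(dir, "rec_a.hea"))
  expect_identical(back$signal, rec$signal)
  expect_equal(back$fs, 500)
  expect_equal(back$age, 63)
  expect_equal(back$sex, "female")
  expect_equal(back$site_id, "site_2")
  expect_false(back$flagged)
})

test_that("CSV records round-trip and keep sidecar metadata", {
  rec <- quantized_record()
  dir <- withr::local_tempdir()
  write_ecg_record(rec, dir, format = "csv")
  back <- read_ecg_record(file.path(dir, "rec_a.csv"))
  expect_equal(back$signal, rec$signal)
  expect_equal(back$fs, 500)
  expect_equal(back$age, 63)
})

test_that("malformed and incomplete records raise named format errors", {
  dir <- withr::local_tempdir()
  bad <- file.path(dir, "bad.csv")
  writeLines(c("amplitude_mv", "0.1", "oops", "0.2"), bad)
  err <- expect_error(read_ecg_record(bad), class = "hrvpipe_format_error")
  expect_match(conditionMessage(err), "line 3")
  expect_match(conditionMessage(err), "amplitude_mv")
  expect_error(read_ecg_record(file.path(dir, "absent.hea")),
               class = "hrvpipe_format_error")
  # missing age -> flagged with warning, not an error
  rec <- quantized_record(); rec$age <- NULL
  write_ecg_record(rec, dir, format = "wfdb")
  expect_warning(back <- read_ecg_record(file.path(dir, "rec_a.hea")),
                 "missing age or sex")
  expect_true(back$flagged)
})

test_that("feature tables round-trip CSV with a fixed column order", {
  tbl <- tibble::tibble(record_id = c("a", "b", "c"), age = c(30, 40, 50.5),
                        sex = c(0, 1, 0), rmssd = c(0.0041, 0.002, 0.08),
                        mean_hr = c(61.25, 50, 48), r_peaks = c(61, 50, 48),
                        target = c(0.9, 0.2, 1e-6))
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(tbl, path)
  expect_length(readLines(path), 4)  # header + 3 rows
  back <- read_feature_table(path)
  expect_equal(as.data.frame(back), as.data.frame(tbl), tolerance = 1e-12)
  # header-only file for an empty table
  write_feature_table(tbl[0, ], path)
  expect_length(readLines(path), 1)
})

test_that("cohort export writes waveforms, metadata and ground truth", {
  coh <- generate_cohort(cohort_config(3, duration_s = 10, seed = 8))
  dir <- withr::local_tempdir()
  write_cohort(coh, dir, format = "csv")
  expect_true(all(file.exists(file.path(
    dir, c("cohort_meta.csv", "ground_truth.csv", "rec_00001.csv")))))
  meta <- readr::read_csv(file.path(dir, "cohort_meta.csv"),
                          show_col_types = FALSE)
  expect_equal(meta$record_id, coh$record_id)
  truth <- readr::read_csv(file.path(dir, "ground_truth.csv"),
                           show_col_types = FALSE)
  expect_equal(truth$r_times_s[truth$record_id == "rec_00002"],
               coh$r_times_s[[2]])
  back <- read_ecg_record(file.path(dir, "rec_00001.csv"))
  expect_equal(back$fs, 500)
  expect_equal(length(back$signal) / 500,
               tail(coh$r_times_s[[1]], 1) + 0.25, tolerance = 0.01)
})
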