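test_that("printed anchor bands carry the published normative values", {
  refs <- default_refs()
  b20 <- refs[refs$age_low == 20, ]
  expect_equal(c(b20$median_low_s, b20$median_high_s), c(0.0041, 0.0048))
  expect_equal(c(b20$range_low_s, b20$range_high_s), c(0.0013, 0.0161))
  b60 <- refs[refs$age_low == 60, ]
  expect_equal(c(b60$range_low_s, b60$range_high_s), c(0.0005, 0.0104))
  expect_equal(b60$median_low_s, 0.00204)
  expect_equal(b60$median_high_s, 0.00207)  # corrected decimal
  # bands partition 20-89 and respect the ordering invariant
  expect_equal(refs$age_low, seq(20, 80, 10))
  expect_true(all(refs$range_low_s < refs$median_low_s))
  expect_true(all(refs$median_low_s <= refs$median_high_s))
  expect_true(all(refs$median_high_s < refs$range_high_s))
  expect_true(all(refs$sigma_low_ms > 0 & refs$sigma_high_ms > 0))
})

test_that("invalid reference files are rejected", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("age_low,age_high,median_low_s,median_high_s,range_low_s,range_high_s",
               "20,40,0.004,0.005,0.001,0.016",
               "35,60,0.003,0.004,0.001,0.012"), path)
  expect_error(reference_bands(path), class = "hrvpipe_invalid_reference")
})

test_that("reference files round-trip through the CSV source", {
  refs <- default_refs()
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(refs[, 1:6], path)
  refs2 <- reference_bands(path)
  expect_equal(refs2$mu_ms, refs$mu_ms, tolerance = 1e-12)
  expect_equal(refs2$sigma_low_ms, refs$sigma_low_ms, tolerance = 1e-12)
})

test_that("the fitted normal reproduces its closed-form parameters", {
  fit <- fit_band_normal(0.0041, 0.0048, 0.0013, 0.0161, coverage = 0.96)
  expect_equal(fit$mu_ms, 4.45)
  expect_equal(fit$sigma_ms, 14.8 / (2 * qnorm(0.98)), tolerance = 1e-12)
  # each side's sigma places its range boundary exactly at |z| = qnorm(0.98)
  expect_equal((fit$mu_ms - 1.3) / fit$sigma_low_ms, qnorm(0.98))
  expect_equal((16.1 - fit$mu_ms) / fit$sigma_high_ms, qnorm(0.98))
  expect_error(fit_band_normal(0.004, 0.004, 0.004, 0.004),
               class = "hrvpipe_invalid_reference")
})

test_that("sigma shrinks monotonically to zero as coverage approaches 1", {
  covs <- c(0.8, 0.9, 0.96, 0.99, 0.9999)
  sig <- vapply(covs, function(cv)
    fit_band_normal(0.0041, 0.0048, 0.0013, 0.0161, cv)$sigma_ms, numeric(1))
  expect_true(all(diff(sig) < 0))
  expect_lt(sig[length(sig)], 2)
})

test_that("typicality score matches its analytic anchor points", {
  b <- default_refs()[1, ]
  expect_equal(typicality_score(b$mu_ms, b)$score, 1)
  at_bounds <- typicality_score(c(1.3, 16.1), b)
  expect_equal(at_bounds$score, c(0.04, 0.04), tolerance = 1e-9)
  expect_true(all(at_bounds$in_range))
  # one side-sigma beyond the upper boundary: boundary score times exp(-1)
  beyond <- typicality_score(16.1 + b$sigma_high_ms, b)
  expect_equal(beyond$score, 0.04 * exp(-1), tolerance = 1e-9)
  expect_false(beyond$in_range)
  expect_equal(beyond$boundary_distance_ms, b$sigma_high_ms)
})

test_that("score is continuous at both range boundaries", {
  b <- default_refs()[1, ]
  for (bd in c(1.3, 16.1)) {
    eps <- 1e-6 * b$sigma_ms
    s <- typicality_score(c(bd - eps, bd + eps), b)$score
    expect_lt(abs(diff(s)), 1e-6)
  }
})

test_that("score decays strictly monotonically outside the range", {
  b <- default_refs()[1, ]
  below <- typicality_score(seq(1.29, 0.01, length.out = 25), b)$score
  above <- typicality_score(seq(16.2, 60, length.out = 25), b)$score
  expect_true(all(diff(below) < 0))
  expect_true(all(diff(above) < 0))
})

test_that("two-sided score is maximal at the mode and symmetric in z", {
  b <- default_refs()[1, ]
  d <- c(0.3, 0.9, 1.7)
  lo <- typicality_score(b$mu_ms - d * b$sigma_low_ms, b)
  hi <- typicality_score(b$mu_ms + d * b$sigma_high_ms, b)
  expect_equal(lo$score, hi$score, tolerance = 1e-12)
  expect_equal(lo$z, -hi$z, tolerance = 1e-12)
  expect_true(all(lo$score < 1))
})

test_that("scores stay in [0,1] for arbitrary non-negative RMSSD", {
  set.seed(31)
  refs <- default_refs()
  for (i in seq_len(nrow(refs))) {
    x <- c(0, runif(300, 0, 500), 1e4)
    for (mode in c("two_sided", "literal_cdf")) {
      s <- typicality_score(x, refs[i, ], mode = mode)$score
      expect_true(all(s >= 0 & s <= 1))
    }
  }
  expect_error(typicality_score(-1, refs[1, ]),
               class = "hrvpipe_invalid_parameter")
})

test_that("literal CDF mode is monotone across the range", {
  b <- default_refs()[1, ]
  x <- seq(1.3, 16.1, length.out = 50)
  s <- typicality_score(x, b, mode = "literal_cdf")$score
  expect_true(all(diff(s) > 0))
})

test_that("draws from the fitted band land in range at the coverage rate", {
  b <- default_refs()[1, ]
  x <- sample_band_rmssd(50000, b, seed = 5)
  frac <- mean(x >= 1000 * b$range_low_s & x <= 1000 * b$range_high_s)
  expect_lt(abs(frac - 0.96), 0.005)
})

test_that("labeling excludes out-of-span ages and scores band centers as 1", {
  refs <- default_refs()
  feats <- tibble::tibble(
    record_id = sprintf("r%d", 1:4),
    age = c(25, 45, 19, 95),
    rmssd = c(refs$mu_ms[refs$age_low == 20],
              refs$mu_ms[refs$age_low == 40], 5, 5) / 1000,
    mean_hr = 60, r_peaks = 60)
  expect_warning(lab <- label_records(feats, refs), "age outside")
  expect_equal(nrow(lab), 2)
  expect_equal(lab$target, c(1, 1))
})
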