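test_that("winsorization caps at the interpolated percentiles", {
  d <- tibble::tibble(x = as.numeric(1:100), const = rep(3, 100))
  out <- winsorize(d, c("x", "const"))
  caps <- attr(out, "caps")
  # sort-based oracle for the linear-interpolation percentile definition
  xs <- sort(d$x)
  oracle <- function(p) {
    h <- (length(xs) - 1) * p + 1
    xs[floor(h)] + (h - floor(h)) * (xs[ceiling(h)] - xs[floor(h)])
  }
  expect_equal(caps$lower[caps$column == "x"], oracle(0.05), tolerance = 1e-12)
  expect_equal(caps$upper[caps$column == "x"], oracle(0.95), tolerance = 1e-12)
  expect_equal(min(out$x), caps$lower[1])
  expect_equal(max(out$x), caps$upper[1])
  expect_equal(out$const, d$const)  # constant column unchanged
  expect_error(winsorize(d, "x", 95, 5), class = "hrvpipe_invalid_parameter")
  expect_error(winsorize(tibble::tibble(x = NA_real_), "x"),
               class = "hrvpipe_invalid_parameter")
})

test_that("random columns are clipped to sort-oracle bounds", {
  set.seed(12)
  d <- tibble::tibble(x = rnorm(501))
  out <- winsorize(d, "x", 5, 95)
  caps <- attr(out, "caps")
  xs <- sort(d$x)
  for (j in 1:2) {
    p <- c(0.05, 0.95)[j]
    h <- (501 - 1) * p + 1
    v <- xs[floor(h)] + (h - floor(h)) * (xs[ceiling(h)] - xs[floor(h)])
    expect_equal(c(caps$lower[1], caps$upper[1])[j], v, tolerance = 1e-12)
  }
  expect_true(all(out$x >= caps$lower[1] & out$x <= caps$upper[1]))
})

test_that("IQR fence mode uses Tukey bounds", {
  d <- tibble::tibble(x = c(1:20, 100))
  out <- winsorize(d, "x", method = "iqr")
  q <- quantile(d$x, c(0.25, 0.75), type = 7)
  expect_equal(max(out$x), unname(q[2] + 1.5 * diff(q)))
})

test_that("Spearman matrix matches the rank formula and flags constants", {
  d <- tibble::tibble(x = c(1, 2, 3), y = c(3, 1, 2))
  m <- spearman_matrix(d)
  expect_equal(m["x", "y"], 1 - 6 * 6 / (3 * 8))  # -0.5 by hand
  expect_equal(diag(m), c(x = 1, y = 1))
  expect_equal(m, t(m))
  expect_warning(m2 <- spearman_matrix(tibble::tibble(x = 1:5, c = rep(1, 5))),
                 "Constant")
  expect_equal(m2["x", "c"], 0)
  expect_error(spearman_matrix(d[1:2, ]), class = "hrvpipe_insufficient_data")
})

test_that("collinear pairs collapse into a mean-of-z-scores feature", {
  set.seed(5)
  x <- rnorm(400)
  d <- tibble::tibble(a = x, b = x + rnorm(400, 0, 0.05), c = rnorm(400))
  out <- collapse_collinear(d, threshold = 0.85)
  expect_setequal(names(out), c("c", "a_b"))
  m <- attr(out, "merges")
  expect_equal(m$new, "a_b")
  rho_pearson <- cor(x, d$b)
  # two unit-variance columns with correlation rho merge to variance (1+rho)/2
  expect_equal(mean(out$a_b^2) - mean(out$a_b)^2, (1 + rho_pearson) / 2,
               tolerance = 0.01)
  # uncorrelated features are untouched
  out2 <- collapse_collinear(tibble::tibble(a = rnorm(100), b = rnorm(100)),
                             threshold = 0.85)
  expect_setequal(names(out2), c("a", "b"))
  # exact duplicate
  out3 <- collapse_collinear(tibble::tibble(a = x, b = x), threshold = 0.85)
  expect_equal(names(out3), "a_b")
})

test_that("the heart-rate/R-peak pair merges under its conventional name", {
  lab <- small_labeled()
  m <- spearman_matrix(lab, c("mean_hr", "r_peaks"))
  expect_gt(m["mean_hr", "r_peaks"], 0.98)
  proc <- small_processed()
  expect_true("r_peak_mean_hr" %in% names(proc))
  expect_false(any(c("mean_hr", "r_peaks") %in% names(proc)))
})

test_that("standardization follows the population-SD convention", {
  d <- tibble::tibble(x = c(0, 10))
  out <- standardize(d, "x")
  expect_equal(out$x, c(-1, 1))
  # idempotence
  out2 <- standardize(out, "x")
  expect_equal(out2$x, out$x, tolerance = 1e-10)
  # train-fitted scaler reapplied to identical rows reproduces the output
  out3 <- standardize(d, "x", scaler = attr(out, "scaler"))
  expect_identical(out3$x, out$x)
  expect_error(standardize(tibble::tibble(x = rep(2, 5)), "x"),
               class = "hrvpipe_invalid_parameter")
})

test_that("processed tables have standardized features and both targets", {
  proc <- small_processed()
  rep_ <- preprocess_report(proc)
  for (col in rep_$scaler$column) {
    expect_lt(abs(mean(proc[[col]])), 1e-10)
    expect_lt(abs(sqrt(mean((proc[[col]] - mean(proc[[col]]))^2)) - 1), 1e-10)
  }
  expect_true(all(proc$target_raw >= 0 & proc$target_raw <= 1))
  expect_true("target" %in% rep_$scaler$column)
})

test_that("the stored report replays the exact transformation", {
  lab <- small_labeled()
  proc <- small_processed()
  replay <- apply_preprocess(lab, preprocess_report(proc))
  expect_equal(as.data.frame(replay[, names(proc)]), as.data.frame(proc),
               tolerance = 1e-14)
  # and the whole pass is deterministic
  proc2 <- preprocess_features(lab)
  expect_identical(as.data.frame(proc2), as.data.frame(proc))
})
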