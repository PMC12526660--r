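test_that("stratified splits are disjoint, sized and reproducible", {
  proc <- small_processed()
  d <- proc[1:100, ]
  sp <- split_train_test(d, test_frac = 0.2, seed = 1)
  expect_equal(nrow(sp$train), 80)
  expect_equal(nrow(sp$test), 20)
  expect_length(intersect(sp$train$record_id, sp$test$record_id), 0)
  sp2 <- split_train_test(d, test_frac = 0.2, seed = 1)
  expect_identical(sp$test$record_id, sp2$test$record_id)
  # per-quintile target proportions in test close to train
  sp3 <- split_train_test(proc, test_frac = 0.2, seed = 2)
  br <- quantile(proc$target, seq(0, 1, 0.2))
  pt <- function(x) prop.table(table(cut(x, br, include.lowest = TRUE)))
  expect_true(all(abs(pt(sp3$test$target) - pt(sp3$train$target)) < 0.05))
  expect_warning(split_train_test(d[1:10, ], seed = 1), "plain random split")
})

test_that("a noise-free linear target is recovered by the linear model", {
  set.seed(2)
  d <- tibble::tibble(x = rnorm(200), target = 2 * x)
  sp <- split_train_test(d, seed = 1)
  m <- fit_regressor(sp$train, "linear")
  ev <- evaluate_regressor(m, sp$test)
  expect_gt(ev$r2, 0.999)
  expect_equal(unname(coef(m$fit)["x"]), 2, tolerance = 1e-8)
})

test_that("rmse, mse and R-squared satisfy their identities", {
  proc <- small_processed()
  sp <- split_train_test(proc, seed = 3)
  for (nm in c("linear", "decision_tree", "random_forest",
               "grad_boost_a", "grad_boost_b")) {
    m <- fit_regressor(sp$train, nm, seed = 3)
    ev <- evaluate_regressor(m, sp$test)
    expect_equal(ev$rmse^2, ev$mse, tolerance = 1e-12)
    y <- sp$test$target
    expect_equal(ev$r2, 1 - ev$mse / mean((y - mean(y))^2), tolerance = 1e-12)
  }
})

test_that("gradient-boosting variants are genuinely different models", {
  proc <- small_processed()
  sp <- split_train_test(proc, seed = 3)
  pa <- predict(fit_regressor(sp$train, "grad_boost_a", seed = 3), sp$test)
  pb <- predict(fit_regressor(sp$train, "grad_boost_b", seed = 3), sp$test)
  expect_false(isTRUE(all.equal(pa, pb)))
})

test_that("unknown models and hyperparameters are rejected", {
  proc <- small_processed()
  expect_error(fit_regressor(proc, "random_forest",
                             list(n_estimators = 100)),
               class = "hrvpipe_invalid_parameter")
  expect_error(fit_regressor(proc, "mystery_model"))
})

test_that("permuting the target destroys held-out performance", {
  proc <- small_processed()
  perm <- proc
  perm$target <- with_seed_sample(perm$target, 77)
  sp <- split_train_test(perm, seed = 5)
  m <- fit_regressor(sp$train, "random_forest", seed = 5)
  expect_lte(evaluate_regressor(m, sp$test)$r2, 0.05)
})

test_that("cross-validation is reproducible and near zero for perfect fits", {
  set.seed(4)
  d <- tibble::tibble(x = rnorm(60), target = 3 * x)
  cv <- cross_validate(d, "linear", k = 5, seed = 9)
  expect_lt(cv$mse_mean, 1e-20)
  expect_lt(cv$mse_var, 1e-20)
  cv2 <- cross_validate(d, "linear", k = 5, seed = 9)
  expect_identical(attr(cv, "per_fold"), attr(cv2, "per_fold"))
  # leave-one-out on a tiny table runs
  tiny <- d[1:8, ]
  expect_silent(cross_validate(tiny, "linear", k = 8, seed = 1))
  expect_error(cross_validate(tiny, "linear", k = 9, seed = 1),
               class = "hrvpipe_invalid_parameter")
  expect_error(cross_validate(tiny, "linear", k = 1, seed = 1),
               class = "hrvpipe_invalid_parameter")
})

test_that("classification metrics match hand-computed confusion counts", {
  perfect <- classification_metrics(c(0.2, 0.8, 0.3, 0.9), c(0.1, 0.7, 0.4, 0.6))
  expect_equal(unlist(perfect[, 1:4]), c(accuracy = 1, precision = 1,
                                         recall = 1, f1 = 1))
  # TP=3 FP=1 FN=1 TN=5 (positive = atypical = below threshold)
  truth <- c(rep(0.2, 4), rep(0.8, 6))
  pred  <- c(0.1, 0.2, 0.3, 0.7, 0.4, rep(0.9, 5))
  m <- classification_metrics(truth, pred)
  expect_equal(m$precision, 0.75)
  expect_equal(m$recall, 0.75)
  expect_equal(m$accuracy, 0.8)
  expect_equal(m$f1, 0.75)
  expect_equal(m$threshold_used, 0.5)
  # anti-predictions on balanced data
  anti <- classification_metrics(c(0.2, 0.2, 0.8, 0.8), c(0.8, 0.8, 0.2, 0.2))
  expect_equal(anti$accuracy, 0)
  expect_warning(one <- classification_metrics(c(0.9, 0.8), c(0.9, 0.2)),
                 "single class")
  expect_equal(one$precision, 0)
  expect_error(classification_metrics(c(-0.1, 0.5), c(0.5, 0.5)),
               class = "hrvpipe_invalid_parameter")
})

test_that("tree importances are normalized and honest about single features", {
  set.seed(6)
  d <- tibble::tibble(x = rnorm(150), target = x^2)
  m <- fit_regressor(d, "random_forest", list(num_trees = 50), seed = 1)
  imp <- feature_importance(m)
  expect_equal(imp$feature, "x")
  expect_equal(imp$importance, 1)
  proc <- small_processed()
  m2 <- fit_regressor(proc, "random_forest", seed = 1)
  imp2 <- feature_importance(m2)
  expect_equal(sum(imp2$importance), 1, tolerance = 1e-9)
  expect_error(feature_importance(fit_regressor(d, "linear")),
               class = "hrvpipe_invalid_parameter")
})

test_that("hyperparameter search improves on defaults with a sane trace", {
  proc <- small_processed()
  expect_error(optimize_rf(proc, n_iter = 3), class = "hrvpipe_invalid_parameter")
  single <- optimize_rf(proc, bounds = list(num_trees = c(90, 90),
                                            max_depth = c(12, 12)),
                        n_iter = 5, seed = 2)
  expect_equal(c(single$best$num_trees, single$best$max_depth), c(90, 12))
  opt <- optimize_rf(proc, n_iter = 7, k = 3, seed = 2)
  expect_true(all(diff(opt$trace$best_so_far) <= 0))
  default_cv <- cross_validate(proc, "random_forest",
                               list(num_trees = 111, max_depth = 26),
                               k = 3, seed = 2)
  expect_lte(opt$best$cv_mse, default_cv$mse_mean + 1e-12)
  expect_true(all(opt$trace$num_trees >= 50 & opt$trace$num_trees <= 300))
  expect_true(all(opt$trace$max_depth >= 5 & opt$trace$max_depth <= 40))
})

test_that("federation degenerates gracefully and mirrors symmetric sites", {
  proc <- small_processed()
  one_site <- dplyr::mutate(proc, site = "site_1")
  fed1 <- federated_fit(one_site, "random_forest",
                        list(num_trees = 60), seed = 4)
  cen <- fit_regressor(one_site, "random_forest",
                       list(num_trees = 60), seed = 4)
  expect_equal(predict(fed1, one_site), predict(cen, one_site),
               tolerance = 1e-12)
  # two identical partitions predict exactly like either site
  dup <- dplyr::bind_rows(dplyr::mutate(proc, site = "a"),
                          dplyr::mutate(proc, site = "b"))
  fed2 <- federated_fit(dup, "random_forest", list(num_trees = 60), seed = 4)
  expect_equal(predict(fed2, proc),
               predict(fed2$site_models[["a"]], proc), tolerance = 1e-9)
  expect_warning(
    federated_fit(dplyr::mutate(proc, site = c("tiny", rep("big", nrow(proc) - 1))),
                  "random_forest", list(num_trees = 30), seed = 1),
    "fewer than")
})

test_that("the full benchmark is deterministic under a fixed seed", {
  proc <- small_processed()
  b1 <- benchmark_models(proc, models = c("linear", "random_forest"),
                         seed = 10, cv_k = 3)
  b2 <- benchmark_models(proc, models = c("linear", "random_forest"),
                         seed = 10, cv_k = 3)
  expect_identical(as.data.frame(tidy(b1)), as.data.frame(tidy(b2)))
  expect_identical(b1$importances, b2$importances)
  expect_s3_class(glance(b1), "tbl_df")
  expect_true(all(tidy(b1)$accuracy >= 0 & tidy(b1)$accuracy <= 1))
})
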