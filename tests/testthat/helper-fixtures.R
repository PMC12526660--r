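# Shared fixtures, built once per test run and memoised.
.fixtures <- new.env(parent = emptyenv())

memo <- function(key, build) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- build()
  .fixtures[[key]]
}

default_refs <- function() {
  memo("refs", function() reference_bands(quiet = TRUE))
}

# A small labeled cohort shared across preprocessing/model tests.
small_labeled <- function() {
  memo("small_labeled", function() {
    refs <- default_refs()
    coh <- generate_cohort(cohort_config(400, seed = 99L), refs = refs)
    label_records(compute_features(coh), refs)
  })
}

small_processed <- function() {
  memo("small_processed", function() preprocess_features(small_labeled()))
}

# The tuned-forest benchmark run shared by the regression and importance
# acceptance checks (built once; ~20 s).
acceptance_fit <- function() {
  memo("acceptance_fit", function() {
    refs <- default_refs()
    coh <- generate_cohort(cohort_config(10000, seed = 42L), refs = refs)
    lab <- label_records(compute_features(coh), refs)
    proc <- preprocess_features(lab)
    sp <- split_train_test(proc, test_frac = 0.2, seed = 42L)
    rf <- fit_regressor(sp$train, "random_forest",
                        list(num_trees = 111, max_depth = 26), seed = 42L)
    list(rf = rf, eval = evaluate_regressor(rf, sp$test))
  })
}

with_seed_sample <- function(x, seed) {
  set.seed(seed)
  sample(x)
}

# Independent naive RMSSD oracle: explicit two-pass loop.
naive_rmssd <- function(rr) {
  s <- 0
  for (i in seq_len(length(rr) - 1L)) s <- s + (rr[i + 1L] - rr[i])^2
  sqrt(s / (length(rr) - 1L))
}
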