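#' Gaussian-process hyperparameter optimization of the random forest
#'
#' Sequential model-based (Bayesian) optimization of the forest's number of
#' trees and maximum depth against cross-validated MSE: a maximin Latin
#' hypercube seeds the design, a Gaussian-process surrogate
#' ([kernlab::gausspr()] with an RBF kernel on the unit cube and a
#' predictive-variance model) is refit after every evaluation, and the next
#' point maximizes expected improvement over a candidate pool. Integer
#' hyperparameters are rounded before evaluation; already-evaluated points
#' are skipped.
#'
#' @param train Training tibble.
#' @param bounds Named list of `c(lower, upper)` bounds; default
#'   `num_trees` in \[50, 300\] and `max_depth` in \[5, 40\]. A degenerate
#'   space (all bounds equal) returns that single point after one
#'   evaluation.
#' @param n_iter Total number of objective evaluations (>= 5).
#' @param k Cross-validation folds per evaluation (default 3).
#' @param seed Integer seed.
#' @param features,target Passed to [cross_validate()].
#' @return A list of class `hrv_opt_trace`: `best` (one-row tibble of the
#'   best hyperparameters and their CV MSE) and `trace` (tibble with one row
#'   per evaluation: hyperparameters, `cv_mse`, non-increasing
#'   `best_so_far`).
#' @export
optimize_rf <- function(train,
                        bounds = list(num_trees = c(50, 300),
                                      max_depth = c(5, 40)),
                        n_iter = 15L, k = 3L, seed = 42L,
                        features = NULL, target = "target") {
  if (n_iter < 5L) {
    abort("n_iter must be at least 5.", class = "hrvpipe_invalid_parameter")
  }
  lo <- vapply(bounds, `[`, numeric(1), 1)
  hi <- vapply(bounds, `[`, numeric(1), 2)
  if (any(hi < lo)) {
    abort("Bounds must be ordered.", class = "hrvpipe_invalid_parameter")
  }
  nm <- names(bounds)
  unscale <- function(u) {
    p <- lo + u * (hi - lo)
    stats::setNames(as.integer(round(p)), nm)
  }
  objective <- function(p) {
    cross_validate(train, "random_forest",
                   hyperparameters = as.list(p), k = k, seed = seed,
                   features = features, target = target)$mse_mean
  }

  if (all(hi == lo)) {
    p <- unscale(rep(0, length(nm)))
    tr <- tibble::as_tibble(as.list(p))
    tr$cv_mse <- objective(p); tr$iter <- 1L; tr$best_so_far <- tr$cv_mse
    return(structure(list(best = tr[, c(nm, "cv_mse")], trace = tr),
                     class = "hrv_opt_trace"))
  }

  d <- length(nm)
  n_init <- max(4L, min(n_iter - 1L, 2L * d + 1L))
  design <- with_local_seed(seed, lhs::maximinLHS(n_init, d))
  # seed the design with the incumbent defaults (clipped into the space) so
  # the search can never end worse than where it started
  incumbent <- vapply(nm, function(p) {
    v <- default_hyper("random_forest")[[p]] %||% mean(c(lo[p], hi[p]))
    min(1, max(0, (v - lo[[p]]) / (hi[[p]] - lo[[p]])))
  }, numeric(1))
  design <- rbind(incumbent, design[-1, , drop = FALSE])
  X <- matrix(numeric(0), ncol = d)
  evals <- list()
  add_eval <- function(u) {
    p <- unscale(u)
    key <- paste(p, collapse = "_")
    if (key %in% vapply(evals, `[[`, character(1), "key")) return(FALSE)
    y <- objective(p)
    evals[[length(evals) + 1L]] <<- list(key = key, u = u, p = p, y = y)
    X <<- rbind(X, u)
    TRUE
  }
  for (i in seq_len(n_init)) add_eval(design[i, ])

  it <- 0L
  while (length(evals) < n_iter && it < 4L * n_iter) {
    it <- it + 1L
    y <- vapply(evals, `[[`, numeric(1), "y")
    cand <- with_local_seed(derive_seed(seed, paste0("cand", it)),
                            lhs::randomLHS(256L, d))
    u_next <- tryCatch({
      gp <- kernlab::gausspr(X, (y - mean(y)) / max(sd(y), 1e-12),
                             kernel = "rbfdot", kpar = list(sigma = 2),
                             variance.model = TRUE, tol = 1e-6)
      mu <- predict(gp, cand) * max(sd(y), 1e-12) + mean(y)
      s <- pmax(predict(gp, cand, type = "sdeviation") * max(sd(y), 1e-12),
                1e-12)
      imp <- min(y) - mu
      z <- imp / s
      ei <- imp * pnorm(z) + s * stats::dnorm(z)
      cand[which.max(ei), ]
    }, error = function(e) cand[1L, ])
    if (!add_eval(u_next)) {
      # duplicate proposal: fall back to the most distant candidate
      dist <- apply(cand, 1, function(u) min(colSums((t(X) - u)^2)))
      add_eval(cand[which.max(dist), ])
    }
  }

  trace <- purrr::map_dfr(evals, function(e) {
    tibble::as_tibble(as.list(e$p)) |> dplyr::mutate(cv_mse = e$y)
  })
  trace$iter <- seq_len(nrow(trace))
  trace$best_so_far <- cummin(trace$cv_mse)
  best <- trace[which.min(trace$cv_mse), c(nm, "cv_mse")]
  structure(list(best = best, trace = trace), class = "hrv_opt_trace")
}

#' @export
print.hrv_opt_trace <- function(x, ...) {
  cat("<hrv_opt_trace>", nrow(x$trace), "evaluations; best:\n")
  print.data.frame(x$best)
  invisible(x)
}
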