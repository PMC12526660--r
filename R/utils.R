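#' @importFrom rlang %||% abort warn .data
#' @importFrom stats quantile qnorm pnorm rnorm runif rlnorm sd var cor predict
#' @importFrom utils head tail
NULL

# Evaluate `expr` under a locally seeded RNG without disturbing the caller's
# RNG state. `seed = NULL` leaves the current stream untouched.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) {
    return(force(expr))
  }
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(expr)
}

# Deterministic per-stage child seeds from a single top-level seed.
# Kept below 2^31 so they are valid R integers.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(as.character(stage)) * seq_along(utf8ToInt(as.character(stage))))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single finite number in [%s, %s].",
                  name, format(lower), format(upper)),
          class = "hrvpipe_invalid_parameter")
  }
  invisible(x)
}

assert_columns <- function(data, cols, what = "data") {
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0L) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")),
          class = "hrvpipe_missing_columns")
  }
  invisible(data)
}
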