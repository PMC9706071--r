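# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, seed >= 0)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Closed-form simple OLS with intercept. Used in tight simulation loops where
# lm()'s model-frame overhead dominates; equivalence with lm() is asserted in
# the test suite.
ols_fit <- function(x, y) {
  n <- length(x)
  stopifnot(n == length(y), n >= 2L)
  xbar <- mean(x)
  ybar <- mean(y)
  sxx <- sum((x - xbar)^2)
  if (sxx <= 0) {
    stop("ols_fit(): predictor has zero variance (all x equal)", call. = FALSE)
  }
  slope <- sum((x - xbar) * (y - ybar)) / sxx
  intercept <- ybar - slope * xbar
  res <- y - intercept - slope * x
  se <- if (n > 2L) sqrt(sum(res^2) / (n - 2L) / sxx) else NA_real_
  list(slope = slope, intercept = intercept, slope_se = se, residuals = res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
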