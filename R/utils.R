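#' Clamp values into a closed interval
#'
#' @param x numeric vector.
#' @param lo,hi interval bounds.
#' @return `x` with values outside `[lo, hi]` replaced by the nearest bound.
#' @keywords internal
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Population variance and covariance (divisor n, matching SS_tot / n).
var_pop <- function(x) {
  m <- mean(x)
  mean((x - m)^2)
}

cov_pop <- function(x, y) {
  mean(x * y) - mean(x) * mean(y)
}

# Deterministic child seeds: spread a user seed into per-task seeds without
# exceeding the 32-bit integer range.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1103515245 + 12345 * as.numeric(k)) %% 2147483647L)
}

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
}
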