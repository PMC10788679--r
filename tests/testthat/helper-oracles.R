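# Independent oracles used to freeze expected values.  These deliberately
# avoid the package's own recursions and formulas.

# Exhaustive-path posterior for the haplotype-copying HMM: enumerates all
# H^M hidden template paths, weighs each by transition and emission
# probabilities, and marginalizes.  Feasible for H <= 4, M <= 5.
enum_posterior <- function(A, target, theta, eps) {
  M <- nrow(A)
  H <- ncol(A)
  paths <- as.matrix(expand.grid(rep(list(seq_len(H)), M)))
  w <- numeric(nrow(paths))
  for (r in seq_len(nrow(paths))) {
    pth <- paths[r, ]
    pr <- 1 / H
    if (M > 1) {
      for (m in 2:M) {
        th <- theta[m - 1]
        pr <- pr * if (pth[m] == pth[m - 1]) (1 - th) + th / H else th / H
      }
    }
    for (m in seq_len(M)) {
      t <- target[m]
      if (!is.na(t)) {
        pr <- pr * if (A[m, pth[m]] == t) 1 - eps[m] else eps[m]
      }
    }
    w[r] <- pr
  }
  post <- matrix(0, M, H)
  for (m in seq_len(M)) {
    for (h in seq_len(H)) post[m, h] <- sum(w[paths[, m] == h])
  }
  post / rowSums(post)
}

enum_hds <- function(A, target, theta, eps) {
  post <- enum_posterior(A, target, theta, eps)
  rowSums(post * A)
}

# Ordinary-least-squares sum-of-squares decomposition of the regression of
# dosage on truth, via lm(): returns the metric quartet computed from
# SS_reg / SS_res / SS_tot and the binomial variance, independently of the
# package's covariance formulas.
ols_oracle <- function(x, y, dose = 1) {
  n <- length(y)
  fit <- lm(y ~ x)
  ss_res <- sum(residuals(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  ss_reg <- ss_tot - ss_res
  p <- mean(y) / dose
  denom <- dose * p * (1 - p)
  list(
    rsq = (ss_tot / n) / denom,
    emprsq = ss_reg / ss_tot,
    mare = (ss_res / n) / denom,
    beta_imp = sqrt((ss_reg / n) / denom)
  )
}

random_metric_pair <- function(n = 50, ploidy_dose = 1) {
  repeat {
    x <- sample(0:ploidy_dose, n, replace = TRUE)
    if (var(x) > 0) break
  }
  q <- runif(n)
  y <- clamp_num(x / ploidy_dose * 0.6 + 0.4 * q, 0, 1) * ploidy_dose
  if (var(y) == 0) y[1] <- y[1] / 2 + 0.25
  list(x = x, y = y)
}

clamp_num <- function(v, lo, hi) pmin(pmax(v, lo), hi)

# reference population variance used by tests (independent of the package's)
var_pop_ref <- function(v) mean((v - mean(v))^2)

random_hmm_instance <- function(H = NULL, M = NULL) {
  if (is.null(H)) H <- sample(1:4, 1)
  if (is.null(M)) M <- sample(2:5, 1)
  A <- matrix(sample(0:1, M * H, replace = TRUE), M, H)
  target <- sample(c(0L, 1L, NA), M, replace = TRUE, prob = c(0.4, 0.4, 0.2))
  if (all(is.na(target))) target[1] <- 1L
  theta <- runif(M - 1, 0.01, 0.9)
  eps <- runif(M, 0.005, 0.3)
  list(A = A, target = target, theta = theta, eps = eps)
}

# Small two-ancestry scene shared by several experiment-level tests.
mini_benchmark <- function(seed = 11L) {
  spec <- panel_spec(
    n_markers = 200L,
    ancestries = list(
      list(label = "A", n_haplotypes = 40L, fst = 0.1, n_founders = 10L,
           n_targets = 10L),
      list(label = "B", n_haplotypes = 40L, fst = 0.1, n_founders = 10L,
           n_targets = 10L)
    ),
    seed = seed
  )
  sim <- build_panel(spec)
  mask <- mask_array(200L, typed_fraction = 0.25, seed = seed + 1L)
  list(sim = sim, mask = mask)
}
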