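test_that("Rsq is the ratio of dosage variance to binomial variance", {
  # perfectly certain, correct dosages at p = 0.5: Var(y) = p(1-p)
  expect_equal(compute_rsq(c(0, 1, 0, 1)), 1.0)
  # constant dosages at p = 0.5 carry no variance
  expect_equal(compute_rsq(rep(0.5, 4)), 0.0)
  # hand-computed: Var = 0.125, p(1-p) = 0.25
  expect_equal(compute_rsq(c(0.1, 0.2, 0.8, 0.9)), 0.5)
  # frequency override shifts only the denominator
  expect_equal(compute_rsq(c(0.1, 0.2, 0.8, 0.9), p = 0.25),
               0.125 / (0.25 * 0.75))
  # monomorphic imputed dosages are a flagged missing value, not an error
  r <- compute_rsq(rep(0, 5))
  expect_true(is.na(r))
  expect_identical(attr(r, "flag"), "monomorphic_imputed")
})

test_that("EmpRsq is the squared Pearson correlation", {
  expect_equal(compute_emprsq(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9)), 0.98)
  expect_equal(compute_emprsq(c(0, 1, 0, 1), c(0, 1, 0, 1)), 1.0)
  # anti-correlated dosages: squared correlation is still 1, but flagged
  r <- compute_emprsq(c(0, 0, 1, 1), c(0.9, 0.8, 0.2, 0.1))
  expect_equal(as.numeric(r), 0.98)
  expect_true(isTRUE(attr(r, "negative_slope")))
  r <- compute_emprsq(c(1, 1, 1, 1), c(0.1, 0.2, 0.8, 0.9))
  expect_true(is.na(r))
  expect_identical(attr(r, "flag"), "monomorphic_true")
})

test_that("MARE and beta_imp follow the closed forms", {
  expect_equal(compute_mare(0.8, 0.75), 0.2)
  expect_equal(compute_mare(123, 1), 0)
  expect_equal(compute_mare(0.5, 0.98), 0.01)
  expect_equal(compute_beta_imp(0.5, 0.5), 0.5)
  expect_equal(compute_beta_imp(0.5, 0.98), 0.7)
  expect_equal(compute_beta_imp(1, 1), 1)
  expect_error(compute_mare(-0.1, 0.5), "rsq")
  expect_error(compute_beta_imp(0.5, 1.2), "emprsq")
})

test_that("worked decomposition matches the independent OLS oracle", {
  x <- c(0, 0, 1, 1)
  y <- c(0.1, 0.2, 0.8, 0.9)
  o <- ols_oracle(x, y)
  expect_equal(o$rsq, 0.5)
  expect_equal(o$emprsq, 0.98)
  expect_equal(o$mare, 0.01)
  expect_equal(o$beta_imp, 0.7)
  d <- decompose_metrics(x, y)
  expect_equal(d$rsq, o$rsq)
  expect_equal(d$emprsq, o$emprsq)
  expect_equal(d$mare, o$mare)
  expect_equal(d$beta_imp, o$beta_imp)
  expect_equal(d$slope, unname(coef(lm(y ~ x))[2]))
  expect_identical(d$flags, "ok")
})

test_that("decompose handles degenerate and negative-slope inputs", {
  d <- decompose_metrics(c(0, 1, 0, 1), c(0, 1, 0, 1))
  expect_equal(unlist(d[c("rsq", "emprsq", "mare", "beta_imp")]),
               c(rsq = 1, emprsq = 1, mare = 0, beta_imp = 1))
  d <- decompose_metrics(c(0, 1, 0, 1), rep(0.5, 4))
  expect_equal(d$rsq, 0)
  expect_true(is.na(d$emprsq))
  expect_identical(d$flags, "monomorphic_imputed")
  # negative correlation: beta_imp not defined, diagnostic flag set
  d <- decompose_metrics(c(0, 0, 1, 1), c(0.9, 0.8, 0.2, 0.1))
  expect_true(is.na(d$beta_imp))
  expect_match(d$flags, "negative_slope")
  expect_lt(d$slope, 0)
})

test_that("decomposition identities hold on random pairs", {
  withr::with_seed(424, {
    for (i in 1:200) {
      dose <- sample(1:2, 1)
      pl <- if (dose == 1) "haploid" else "diploid"
      pr <- random_metric_pair(n = sample(10:80, 1), ploidy_dose = dose)
      d <- decompose_metrics(pr$x, pr$y, ploidy = pl)
      if (d$flags != "ok") next
      # Rsq = EmpRsq * Rsq + MARE, exactly
      expect_equal(d$rsq, d$emprsq * d$rsq + d$mare, tolerance = 1e-12)
      # ranges
      expect_gte(d$mare, 0)
      expect_lte(d$mare, d$rsq + 1e-12)
      expect_lte(d$beta_imp, sqrt(d$rsq) + 1e-12)
      expect_lte(d$emprsq, 1 + 1e-12)
      # matches the OLS sum-of-squares route
      o <- ols_oracle(pr$x, pr$y, dose = dose)
      expect_equal(d$rsq, o$rsq, tolerance = 1e-9)
      expect_equal(d$emprsq, o$emprsq, tolerance = 1e-9)
      expect_equal(d$mare, o$mare, tolerance = 1e-9)
      expect_equal(d$beta_imp, o$beta_imp, tolerance = 1e-9)
    }
  })
})

test_that("Rsq = slope^2 + MARE when the allele frequencies agree", {
  # beta_imp = sqrt(EmpRsq * Rsq) equals the raw regression slope exactly
  # when Var(x) matches the binomial variance at the dosage AAF; then
  # Rsq decomposes as slope^2 + MARE
  withr::with_seed(77, {
    for (i in 1:50) {
      n <- 40
      x <- sample(0:1, n, replace = TRUE)
      if (var(x) == 0) next
      y <- x * 0.8 + 0.1
      d <- decompose_metrics(x, y, p = mean(x))
      expect_equal(d$beta_imp, abs(d$slope), tolerance = 1e-9)
      expect_equal(d$rsq, d$slope^2 + d$mare, tolerance = 1e-9)
    }
  })
  # when the AAFs differ the discrepancy is exactly the Var(x)/(p(1-p))
  # ratio applied to the slope term
  x <- c(0, 0, 1, 1)
  y <- c(0.1, 0.2, 0.8, 0.9) * 0.8
  d <- decompose_metrics(x, y)
  ratio <- var_pop_ref(x) / (d$aaf * (1 - d$aaf))
  expect_equal(d$rsq, d$slope^2 * ratio + d$mare, tolerance = 1e-9)
  expect_equal(d$beta_imp, abs(d$slope) * sqrt(ratio), tolerance = 1e-9)
})

test_that("diploid metrics rescale the binomial variance", {
  x <- c(0, 1, 1, 2, 2, 0)
  y <- c(0.1, 0.9, 1.2, 1.8, 1.9, 0.2)
  d <- decompose_metrics(x, y, ploidy = "diploid")
  p <- mean(y) / 2
  expect_equal(d$rsq, var_pop_ref(y) / (2 * p * (1 - p)))
  expect_equal(d$emprsq, cor(x, y)^2)
  expect_equal(d$mare, (1 - d$emprsq) * d$rsq, tolerance = 1e-12)
  o <- ols_oracle(x, y, dose = 2)
  expect_equal(d$rsq, o$rsq)
  expect_equal(d$mare, o$mare, tolerance = 1e-12)
})

test_that("matrix decomposition agrees with the per-variant path", {
  withr::with_seed(5150, {
    truth <- matrix(sample(0:1, 30 * 25, replace = TRUE), 30, 25)
    dosage <- matrix(runif(30 * 25), 30, 25)
    truth[3, ] <- 0L          # monomorphic truth
    dosage[4, ] <- 0.4        # constant dosages
    rec <- decompose_matrix(truth, dosage)
    for (i in seq_len(nrow(truth))) {
      d <- decompose_metrics(truth[i, ], dosage[i, ])
      expect_equal(rec$rsq[i], d$rsq, tolerance = 1e-12)
      expect_equal(rec$emprsq[i], d$emprsq, tolerance = 1e-12)
      expect_equal(rec$mare[i], d$mare, tolerance = 1e-12)
      expect_equal(rec$beta_imp[i], d$beta_imp, tolerance = 1e-12)
      expect_identical(rec$flags[i], d$flags)
    }
  })
})

test_that("well-calibrated posteriors equalize Rsq and EmpRsq as n grows", {
  # y is the posterior allele probability and x a Bernoulli draw from it:
  # E[x | y] = y, the well-calibration condition
  withr::with_seed(909, {
    n <- 10000
    y <- rbeta(n, 0.8, 0.8)
    x <- rbinom(n, 1, y)
    d <- decompose_metrics(x, y)
    expect_lt(abs(d$rsq - d$emprsq), 0.05)
  })
})

test_that("theoretical surfaces evaluate the closed forms on a grid", {
  g <- theoretical_surfaces(c(0, 0.5, 1), c(0, 0.5, 1))
  expect_equal(nrow(g), 9)
  diag1 <- g[g$rsq == 1 & g$emprsq == 1, ]
  expect_equal(diag1$mare, 0)
  expect_equal(diag1$beta_imp, 1)
  diagv <- g[g$rsq == 0.5 & g$emprsq == 0.5, ]
  expect_equal(diagv$mare, 0.5 * (1 - 0.5))
  expect_equal(diagv$beta_imp, 0.5)
  expect_true(all(g$mare[g$rsq == 0] == 0))
  expect_true(all(g$beta_imp[g$rsq == 0] == 0))
  expect_error(theoretical_surfaces(-1, 0.5), "rsq")
})
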