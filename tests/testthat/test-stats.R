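test_that("D'Agostino-Pearson omnibus matches the frozen reference", {
  # reference statistic and p computed independently with the standard
  # skewness/kurtosis transformations (cross-checked against scipy's
  # normaltest to 10 decimals on this fixture)
  x <- c(2.1, 3.4, 1.9, 5.6, 4.4, 3.3, 2.8, 6.1, 3.9, 4.2,
         2.2, 3.1, 5.0, 4.8, 1.5, 3.7, 2.9, 4.1, 3.5, 7.2)
  r <- dagostino_pearson(x)
  expect_equal(r$statistic, 1.7020501124, tolerance = 1e-9)
  expect_equal(r$p_value, 0.4269770321, tolerance = 1e-9)
  expect_error(dagostino_pearson(rnorm(5)), "n >= 8")
  expect_error(dagostino_pearson(rep(1, 20)), "degenerate")
})

test_that("log_transform_check inverts exponentials and is calibrated", {
  set.seed(5)
  z <- rnorm(100)
  out <- log_transform_check(exp(z))
  expect_equal(out$log_values, z)
  expect_error(log_transform_check(c(1, -2, 3)))
  # constant vector: transform returned, test flagged
  cst <- log_transform_check(rep(2, 20))
  expect_true(cst$flagged)
  # log-normal data: post-transform normality rate consistent with the
  # nominal 95% within 3 binomial SE (400 replicates)
  set.seed(11)
  frac <- mean(replicate(400, log_transform_check(exp(rnorm(500)))$normality_p > 0.05))
  expect_gte(frac, 0.95 - 3 * sqrt(0.95 * 0.05 / 400))
})

test_that("rm_anova_tukey agrees with the brute-force SS oracle", {
  # hand-scale block
  set.seed(2)
  b <- matrix(rnorm(12, 10, 2), 4, 3)
  r <- rm_anova_tukey(b)
  o <- oracle_rm_anova_F(b)
  expect_equal(r$F, o$F, tolerance = 1e-10)
  expect_equal(r$p_value, o$p, tolerance = 1e-10)
  # property: 100 random blocks with n <= 6 agree to 1e-8
  set.seed(13)
  for (i in 1:100) {
    n <- sample(3:6, 1)
    b <- matrix(rnorm(3 * n, 50, 10), n, 3) + rnorm(n, 0, 5)
    r <- rm_anova_tukey(b)
    o <- oracle_rm_anova_F(b)
    expect_equal(r$F, o$F, tolerance = 1e-8)
    expect_equal(r$p_value, o$p, tolerance = 1e-8)
    expect_true(all(r$tukey$p_adj >= 0 & r$tukey$p_adj <= 1))
  }
})

test_that("rm_anova_tukey handles degenerate blocks", {
  ident <- matrix(rep(c(1, 2, 3, 4), 3), ncol = 3)
  r <- rm_anova_tukey(ident)
  expect_equal(r$F, 0)
  expect_equal(r$p_value, 1)
  # between-condition effect with zero error: flagged, no exception
  zerr <- outer(c(1, 2, 3), c(0, 5, 10), "+")
  r2 <- rm_anova_tukey(zerr)
  expect_true(r2$flagged)
  # Greenhouse-Geisser epsilon stays in [1/(k-1), 1]; F is unchanged
  set.seed(3)
  b <- matrix(rnorm(30, 10), 10, 3)
  rg <- rm_anova_tukey(b, correction = "gg")
  expect_gte(rg$epsilon, 0.5)
  expect_lte(rg$epsilon, 1)
  expect_equal(rg$F, rm_anova_tukey(b)$F)
  expect_true(rg$p_value >= 0 && rg$p_value <= 1)
})

test_that("unpaired log t-test matches the closed-form oracle", {
  a <- c(34.1, 40.2, 38.8, 35.0, 41.7, 36.2)
  b <- c(42.0, 45.3, 39.8, 47.1, 44.0)
  r <- unpaired_t_log(a, b)
  o <- oracle_t_test(log(a), log(b))
  expect_equal(r$statistic, o$t, tolerance = 1e-12)
  expect_equal(r$p_value, o$p, tolerance = 1e-12)
  # identical groups
  same <- unpaired_t_log(a, a)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  # scale invariance after log transform
  r2 <- unpaired_t_log(10 * a, 10 * b)
  expect_equal(r2$statistic, r$statistic, tolerance = 1e-10)
  # simulated group difference at the configured deep-zone T2 contrast is
  # detected in the majority of replicates
  set.seed(19)
  hits <- mean(replicate(200, {
    g1 <- pmax(rnorm(27, 35.1, 5.8), 1); g2 <- pmax(rnorm(22, 39.9, 7.3), 1)
    unpaired_t_log(g1, g2)$p_value <= 0.05
  }))
  expect_gt(hits, 0.5)
})

test_that("spearman matches the rank-formula oracle including ties", {
  x <- c(1, 2, 2, 3, 4, 5, 5, 5, 6, 7)
  y <- c(2, 1, 4, 3, 6, 5, 8, 7, 9, 9)
  r <- spearman(x, y)
  o <- oracle_spearman(x, y)
  expect_equal(r$rho, o$rho, tolerance = 1e-12)
  expect_equal(r$p_value, o$p, tolerance = 1e-12)
  # also agrees with the established implementation
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  expect_equal(r$rho, unname(ct$estimate), tolerance = 1e-12)
  # monotone pairs
  expect_equal(spearman(1:8, (1:8)^3)$rho, 1)
  expect_equal(spearman(1:8, rev(1:8))$rho, -1)
  expect_true(spearman(rep(1, 5), 1:5)$flagged)
})

test_that("sample_size_unpaired searches the noncentral-t power curve", {
  expect_equal(sample_size_unpaired(0.9, 0.05, 0.8), 34)
  expect_equal(sample_size_unpaired(0.8, 0.05, 0.8), 26)
  # the returned n is minimal under the direct power oracle
  n <- sample_size_unpaired(0.9, 0.05, 0.8)
  expect_gte(oracle_power_two_sample(n, 0.8), 0.9)
  expect_lt(oracle_power_two_sample(n - 1, 0.8), 0.9)
  # monotonicity: non-increasing in d and alpha, non-decreasing in power
  expect_lte(sample_size_unpaired(0.9, 0.05, 1.2), 34)
  expect_lte(sample_size_unpaired(0.9, 0.10, 0.8), 34)
  expect_gte(sample_size_unpaired(0.95, 0.05, 0.8), 34)
  expect_equal(sample_size_unpaired(0.9, 0.05, 10), 2)
})

test_that("significance stratification follows the reporting convention", {
  expect_equal(significance_label(c(0.04, 0.009, 0.0005, 0.2, NA)),
               c("*", "**", "***", "ns", ""))
})

test_that("battery wrappers produce one row per tested cell", {
  cfg <- cohort_config(n_int = 8, n_deg = 8, seed = 23)
  co <- generate_cohort(cfg, render = FALSE)
  w <- loading_response_table(cohort_truth_table(co))
  lr <- loading_response_tests(w)
  expect_equal(nrow(lr), 3 * 4 * 3)   # groups x parameters x zones
  expect_true(all(lr$p_value >= 0 & lr$p_value <= 1))
  gc <- group_comparison_tests(w)
  expect_equal(nrow(gc), 4 * 3)
  expect_true(all(gc$p_value >= 0 & gc$p_value <= 1))
})
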