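test_that("mankin_sum checks ranges and sums", {
  expect_equal(mankin_sum(6, 3, 4, 1), 14L)
  expect_equal(mankin_sum(0, 0, 0, 0), 0L)
  expect_equal(mankin_sum(2, 1, 1, 0), 4L)
  expect_error(mankin_sum(7, 0, 0, 0), "out of range")
  expect_error(mankin_sum(0, 0, 0, 2), "out of range")
})

test_that("dichotomize maps sum-score ranges to study groups", {
  expect_equal(dichotomize(0:4), rep("int", 5))
  expect_equal(dichotomize(5:8), rep("deg", 4))
  expect_equal(dichotomize(9), "out-of-study")
  expect_error(dichotomize(-1))
  expect_error(dichotomize(15))
})

test_that("interval_from_int builds M +/- SD intervals on both scales", {
  # constant vector: degenerate zero-width interval
  iv0 <- interval_from_int(rep(7, 5), scale = "linear")
  expect_equal(c(iv0$lower, iv0$upper), c(7, 7))
  # linear arithmetic
  v <- c(90, 100, 110)
  iv <- interval_from_int(v, scale = "linear")
  expect_equal(iv$lower, 100 - 10)
  expect_equal(iv$upper, 100 + 10)
  # a sample with mean 734.5 and SD 121.3 gives 613.2 / 855.8 (one decimal)
  v2 <- 734.5 + 121.3 * c(-1, 0, 1)  # mean 734.5, sd 121.3
  expect_equal(sd(v2), 121.3, tolerance = 1e-9)
  iv2 <- interval_from_int(v2, scale = "linear")
  expect_equal(round(iv2$lower, 1), 613.2)
  expect_equal(round(iv2$upper, 1), 855.8)
  # log scale: exp(m +/- s) of log-values
  lv <- c(50, 100, 200)
  iv3 <- interval_from_int(lv, scale = "log")
  m <- mean(log(lv)); s <- sd(log(lv))
  expect_equal(iv3$lower, exp(m - s))
  expect_equal(iv3$upper, exp(m + s))
  expect_error(interval_from_int(c(5), scale = "linear"))
  expect_error(interval_from_int(c(-1, 2, 3), scale = "log"))
})

test_that("classify is inclusive at the bounds and flags missing values", {
  iv <- interval_from_int(c(90, 100, 110), scale = "linear")
  expect_equal(classify(iv$lower, iv), "positive")
  expect_equal(classify(iv$upper, iv), "positive")
  expect_equal(classify(900, interval_from_int(734.5 + 121.3 * c(-1, 0, 1),
                                               scale = "linear")), "negative")
  iv0 <- interval_from_int(rep(7, 5), scale = "linear")
  expect_equal(classify(c(7, 7.01), iv0), c("positive", "negative"))
  expect_true(is.na(classify(NA, iv)))
})

test_that("sens_spec agrees with the confusion-matrix oracle", {
  expect_equal(sens_spec(c("positive", "negative", "negative", "negative"),
                         c("int", "int", "deg", "deg"))[c("sensitivity", "specificity")],
               list(sensitivity = 0.5, specificity = 1.0))
  # boundary classifiers
  allpos <- sens_spec(rep("positive", 6), c(rep("int", 3), rep("deg", 3)))
  expect_equal(allpos$sensitivity, 1)
  expect_equal(allpos$specificity, 0)
  # 1000 random seeded label vectors against the oracle
  set.seed(41)
  for (i in 1:1000) {
    n <- sample(2:10, 1)
    pred <- sample(c("positive", "negative"), n, replace = TRUE)
    tr <- sample(c("int", "deg"), n, replace = TRUE)
    got <- sens_spec(pred, tr)
    want <- oracle_confusion(pred, tr)
    expect_identical(as.numeric(c(got$tp, got$fn, got$tn, got$fp)),
                     as.numeric(c(want$tp, want$fn, want$tn, want$fp)))
  }
  expect_error(sens_spec(c("positive"), c("int", "deg")), "length mismatch")
})

test_that("combination rules and their dominance properties hold", {
  expect_equal(combine_tests(c("positive", "negative"), c("negative", "negative"),
                             rule = "believe_positive"),
               c("positive", "negative"))
  a <- c("positive", "negative", "positive")
  expect_equal(combine_tests(a, a, rule = "believe_positive"), a)
  expect_equal(combine_tests(a, a, rule = "believe_negative"), a)
  # exhaustive dominance over all (truth, a, b) configurations up to n = 4:
  # believe-positive never decreases sensitivity / never increases
  # specificity relative to either component, and symmetrically for
  # believe-negative; violations are counted and must be zero
  lab <- c("positive", "negative")
  violations <- 0L
  for (n in 1:4) {
    cfgs <- as.matrix(expand.grid(rep(list(1:2), 3 * n)))
    for (i in seq_len(nrow(cfgs))) {
      v <- cfgs[i, ]
      tr <- c("int", "deg")[v[1:n]]
      ta <- lab[v[(n + 1):(2 * n)]]
      tb <- lab[v[(2 * n + 1):(3 * n)]]
      if (!any(tr == "int") || !any(tr == "deg")) next
      sa <- sens_spec(ta, tr); sb <- sens_spec(tb, tr)
      bp <- sens_spec(combine_tests(ta, tb, rule = "believe_positive"), tr)
      bn <- sens_spec(combine_tests(ta, tb, rule = "believe_negative"), tr)
      bad <- bp$sensitivity < max(sa$sensitivity, sb$sensitivity) ||
        bp$specificity > min(sa$specificity, sb$specificity) ||
        bn$specificity < max(sa$specificity, sb$specificity) ||
        bn$sensitivity > min(sa$sensitivity, sb$sensitivity)
      if (bad) violations <- violations + 1L
    }
  }
  expect_identical(violations, 0L)
  # associative fold for k = 3 components
  set.seed(43)
  t1 <- sample(lab, 30, TRUE); t2 <- sample(lab, 30, TRUE); t3 <- sample(lab, 30, TRUE)
  expect_equal(combine_tests(t1, t2, t3, rule = "believe_positive"),
               combine_tests(combine_tests(t1, t2, rule = "believe_positive"), t3,
                             rule = "believe_positive"))
  expect_error(combine_tests(c("positive"), c("positive", "negative")))
})

test_that("intact training samples fall inside their own interval at the Gaussian rate", {
  set.seed(47)
  v <- rnorm(500, 100, 10)
  iv <- interval_from_int(v, scale = "linear")
  inside <- mean(classify(v, iv) == "positive")
  expect_gt(inside, 0.64)   # ~0.683 expected as n grows
})

test_that("separable zero-noise cohort yields a perfect classifier", {
  # deg group configured strictly outside the int interval, no noise anywhere
  p <- default_group_params()
  p$sd_d0 <- 0
  p$mean_d0[p$group == "deg"] <- p$mean_d0[p$group == "deg"] * 3
  p$`mean_d2.5`[p$group == "deg"] <- p$`mean_d2.5`[p$group == "deg"] * 3
  p$`mean_d5.0`[p$group == "deg"] <- p$`mean_d5.0`[p$group == "deg"] * 3
  cfg <- cohort_config(n_int = 4, n_deg = 4, params = p, shift_sd_log = 0,
                       noise_sigma = 0, curve_noise_sd = 0, seed = 3)
  co <- generate_cohort(cfg, render = FALSE)
  w <- loading_response_table(cohort_truth_table(co))
  rep <- diagnostic_report(w, zone = "ECS", scale = "log")
  single <- rep$performance[rep$performance$rule == "single" &
                              !grepl("delta", rep$performance$test), ]
  expect_true(all(single$sensitivity == 1))
  expect_true(all(single$specificity == 1))
})
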