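#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the transformed skewness statistic (D'Agostino) and the
#' transformed kurtosis statistic (Anscombe-Glynn) into
#' `K^2 = Z1^2 + Z2^2`, referred to a chi-squared distribution with 2 df.
#' Requires n >= 8 for the kurtosis approximation.
#'
#' @param x numeric vector.
#' @return list with `statistic` (K^2), `p_value`, `z_skew`, `z_kurt`, `n`.
#' @export
dagostino_pearson <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 8) stop("D'Agostino-Pearson test requires n >= 8")
  if (stats::sd(x) == 0) stop("degenerate (constant) sample")
  m <- mean(x)
  m2 <- mean((x - m)^2); m3 <- mean((x - m)^3); m4 <- mean((x - m)^4)
  # skewness branch
  b1 <- m3 / m2^1.5
  y <- b1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  alpha <- sqrt(2 / (w2 - 1))
  z1 <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))
  # kurtosis branch
  b2 <- m4 / m2^2
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xs <- (b2 - eb2) / sqrt(vb2)
  sqb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sqb1 * (2 / sqb1 + sqrt(1 + 4 / sqb1^2))
  z2 <- ((1 - 2 / (9 * a)) -
           ((1 - 2 / a) / (1 + xs * sqrt(2 / (a - 4))))^(1 / 3)) /
    sqrt(2 / (9 * a))
  k2 <- z1^2 + z2^2
  list(statistic = k2, p_value = stats::pchisq(k2, df = 2, lower.tail = FALSE),
       z_skew = z1, z_kurt = z2, n = n)
}

#' Log-transform with normality confirmation
#'
#' Natural-log transform of positive data followed by the
#' D'Agostino-Pearson omnibus test on the transformed values. For n < 8 the
#' transform is still returned and the test flagged unavailable.
#'
#' @param values positive numeric vector.
#' @return list with `log_values`, `normality_p` (NA if unavailable) and
#'   `flagged` (TRUE when the test could not be run).
#' @export
log_transform_check <- function(values) {
  if (any(!is.finite(values)) || any(values <= 0))
    stop("log transform requires finite positive values")
  lv <- log(values)
  if (length(lv) < 8 || stats::sd(lv) == 0)
    return(list(log_values = lv, normality_p = NA_real_, flagged = TRUE))
  t <- dagostino_pearson(lv)
  list(log_values = lv, normality_p = t$p_value, flagged = FALSE)
}

#' One-way repeated-measures ANOVA with Tukey post-tests
#'
#' Within-subject ANOVA across the displacement conditions: the subject sum
#' of squares is removed, `F = MS_condition / MS_error` with
#' `df = (k - 1), (n - 1)(k - 1)`, and Tukey-adjusted pairwise comparisons
#' are computed on the within-subject error term via the studentized range
#' distribution. A Greenhouse-Geisser sphericity correction is available but
#' off by default.
#'
#' @param block numeric matrix, subjects in rows, conditions in columns
#'   (complete cases only), n >= 3 rows and >= 2 columns.
#' @param correction `"none"` (default) or `"gg"`.
#' @return list with `F`, `df1`, `df2`, `p_value`, `means`, `epsilon`,
#'   `tukey` (data.frame: pair, diff, q, p_adj), `flagged`.
#' @export
rm_anova_tukey <- function(block, correction = c("none", "gg")) {
  correction <- match.arg(correction)
  block <- as.matrix(block)
  if (any(!is.finite(block))) stop("block must be complete (no missing cells)")
  n <- nrow(block); k <- ncol(block)
  if (n < 3 || k < 2) stop("need >= 3 subjects and >= 2 conditions")
  cm <- colMeans(block); sm <- rowMeans(block); gm <- mean(block)
  ss_cond <- n * sum((cm - gm)^2)
  ss_subj <- k * sum((sm - gm)^2)
  ss_tot <- sum((block - gm)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  df1 <- k - 1; df2 <- (n - 1) * (k - 1)
  ms_err <- ss_err / df2
  cond <- colnames(block) %||% paste0("c", seq_len(k))
  pairs <- utils::combn(k, 2)
  if (ss_cond <= 1e-12 * max(ss_tot, 1)) {
    tk <- data.frame(pair = paste(cond[pairs[1, ]], cond[pairs[2, ]], sep = "-"),
                     diff = cm[pairs[2, ]] - cm[pairs[1, ]],
                     q = 0, p_adj = 1)
    return(list(F = 0, df1 = df1, df2 = df2, p_value = 1, means = cm,
                epsilon = 1, tukey = tk, flagged = FALSE))
  }
  if (ms_err <= 0) {
    return(list(F = Inf, df1 = df1, df2 = df2, p_value = NA_real_, means = cm,
                epsilon = NA_real_, tukey = NULL, flagged = TRUE))
  }
  f <- (ss_cond / df1) / ms_err
  eps <- 1
  if (correction == "gg") {
    # Greenhouse-Geisser epsilon from the condition covariance matrix
    s <- stats::cov(block)
    sbar <- mean(s)
    rowbar <- rowMeans(s)
    eps <- (k * (mean(diag(s)) - sbar))^2 /
      ((k - 1) * (sum(s^2) - 2 * k * sum(rowbar^2) + k^2 * sbar^2))
    eps <- min(max(eps, 1 / (k - 1)), 1)
  }
  p <- stats::pf(f, df1 * eps, df2 * eps, lower.tail = FALSE)
  se <- sqrt(ms_err / n)
  qstat <- abs(cm[pairs[2, ]] - cm[pairs[1, ]]) / se
  tk <- data.frame(pair = paste(cond[pairs[1, ]], cond[pairs[2, ]], sep = "-"),
                   diff = cm[pairs[2, ]] - cm[pairs[1, ]],
                   q = qstat,
                   p_adj = stats::ptukey(qstat, nmeans = k, df = df2,
                                         lower.tail = FALSE),
                   row.names = NULL)
  list(F = f, df1 = df1, df2 = df2, p_value = p, means = cm, epsilon = eps,
       tukey = tk, flagged = FALSE)
}

#' Two-tailed unpaired t-test on log-transformed data
#'
#' Student's (equal-variance) two-sample t-test after natural-log transform,
#' the group-comparison test of the unloaded parameter tables.
#'
#' @param group_a,group_b positive numeric vectors, each n >= 2.
#' @return list with `statistic` (t), `df`, `p_value`, and the group means on
#'   the original scale.
#' @export
unpaired_t_log <- function(group_a, group_b) {
  stopifnot(length(group_a) >= 2, length(group_b) >= 2,
            all(group_a > 0), all(group_b > 0))
  la <- log(group_a); lb <- log(group_b)
  if (stats::sd(c(la, lb)) == 0)
    return(list(statistic = 0, df = length(la) + length(lb) - 2, p_value = 1,
                mean_a = mean(group_a), mean_b = mean(group_b)))
  tt <- stats::t.test(la, lb, var.equal = TRUE)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, mean_a = mean(group_a), mean_b = mean(group_b))
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Tie-corrected Spearman rho (Pearson correlation of mid-ranks) with the
#' two-tailed p-value from the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))`.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list with `rho`, `p_value`, `n`, `flagged` (TRUE when either
#'   vector is constant and rho is undefined).
#' @export
spearman <- function(x, y) {
  n <- length(x)
  stopifnot(length(y) == n, n >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = NA_real_, p_value = NA_real_, n = n, flagged = TRUE))
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p_value = p, n = n, flagged = FALSE)
}

#' Minimum per-group n for a two-sample t-test by noncentral-t power
#'
#' Smallest integer n per group at which the two-sided two-sample t-test
#' with standardized effect size d and significance level alpha reaches the
#' requested power, evaluated exactly via the noncentral t distribution
#' (noncentrality `d * sqrt(n / 2)`, df `2n - 2`).
#'
#' @param power target power in (0, 1).
#' @param alpha two-sided type-I error in (0, 1).
#' @param effect_size_d standardized mean difference, > 0.
#' @param n_max search bound.
#' @return integer sample size per group.
#' @export
sample_size_unpaired <- function(power, alpha, effect_size_d, n_max = 1e5) {
  stopifnot(power > 0, power < 1, alpha > 0, alpha < 1, effect_size_d > 0)
  for (n in 2:n_max) {
    df <- 2 * n - 2
    ncp <- effect_size_d * sqrt(n / 2)
    crit <- stats::qt(1 - alpha / 2, df)
    pw <- stats::pt(crit, df, ncp = ncp, lower.tail = FALSE) +
      stats::pt(-crit, df, ncp = ncp)
    if (pw >= power) return(n)
  }
  stop("requested power unreachable within n_max")
}

#' Significance stars
#'
#' The stratification `p <= 0.05` (*), `<= 0.01` (**), `<= 0.001` (***).
#' @param p p-value(s).
#' @export
significance_label <- function(p) {
  ifelse(is.na(p), "",
         ifelse(p <= 0.001, "***", ifelse(p <= 0.01, "**",
                ifelse(p <= 0.05, "*", "ns"))))
}

#' Loading-response significance battery
#'
#' For every (group, parameter, zone) cell - plus the pooled "all" group -
#' runs the repeated-measures ANOVA with Tukey post-tests across the three
#' displacement positions on log-transformed per-sample values, reproducing
#' the structure of the loading-response table.
#'
#' @param wide a per-sample wide table from [loading_response_table()].
#' @param correction sphericity correction, passed to [rm_anova_tukey()].
#' @return tidy data.frame: `group`, `parameter`, `zone`, `n`, group means at
#'   the three displacements, `F`, `p_value`, the three Tukey-adjusted
#'   pairwise p-values and a significance label.
#' @export
loading_response_tests <- function(wide, correction = "none") {
  out <- list()
  for (g in c("all", "int", "deg")) {
    sub_g <- if (g == "all") wide else wide[wide$group == g, ]
    for (par in unique(wide$parameter)) for (zn in unique(wide$zone)) {
      s <- sub_g[sub_g$parameter == par & sub_g$zone == zn, ]
      s <- s[stats::complete.cases(s[, c("d0", "d2.5", "d5.0")]), ]
      if (nrow(s) < 3) next
      block <- log(as.matrix(s[, c("d0", "d2.5", "d5.0")]))
      r <- rm_anova_tukey(block, correction = correction)
      out[[length(out) + 1]] <- data.frame(
        group = g, parameter = par, zone = zn, n = nrow(s),
        mean_d0 = mean(s$d0), `mean_d2.5` = mean(s$`d2.5`),
        `mean_d5.0` = mean(s$`d5.0`),
        F = r$F, p_value = r$p_value,
        p_d0_d2.5 = if (!is.null(r$tukey)) r$tukey$p_adj[1] else NA_real_,
        p_d0_d5.0 = if (!is.null(r$tukey)) r$tukey$p_adj[2] else NA_real_,
        p_d2.5_d5.0 = if (!is.null(r$tukey)) r$tukey$p_adj[3] else NA_real_,
        label = significance_label(r$p_value),
        check.names = FALSE)
    }
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Unloaded group comparison battery
#'
#' Unpaired log-scale t-tests of int versus deg for every (parameter, zone)
#' at the unloaded position, mirroring the baseline parameter table.
#'
#' @param wide a per-sample wide table from [loading_response_table()].
#' @return tidy data.frame with group means, SDs, t, p and label.
#' @export
group_comparison_tests <- function(wide) {
  out <- list()
  for (par in unique(wide$parameter)) for (zn in unique(wide$zone)) {
    s <- wide[wide$parameter == par & wide$zone == zn & !is.na(wide$d0), ]
    a <- s$d0[s$group == "int"]; b <- s$d0[s$group == "deg"]
    if (length(a) < 2 || length(b) < 2) next
    tt <- unpaired_t_log(a, b)
    out[[length(out) + 1]] <- data.frame(
      parameter = par, zone = zn,
      mean_int = mean(a), sd_int = stats::sd(a),
      mean_deg = mean(b), sd_deg = stats::sd(b),
      t = tt$statistic, p_value = tt$p_value,
      label = significance_label(tt$p_value))
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
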