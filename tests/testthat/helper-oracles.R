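# Independent oracles used to cross-check package implementations.
# These deliberately re-derive each quantity from first principles
# (explicit loops, closed forms) rather than calling the code under test.

# brute-force sums-of-squares decomposition for a one-way within-subject design
oracle_rm_anova_F <- function(block) {
  n <- nrow(block); k <- ncol(block)
  gm <- mean(block)
  ss_cond <- 0
  for (j in 1:k) ss_cond <- ss_cond + n * (mean(block[, j]) - gm)^2
  ss_subj <- 0
  for (i in 1:n) ss_subj <- ss_subj + k * (mean(block[i, ]) - gm)^2
  ss_tot <- 0
  for (i in 1:n) for (j in 1:k) ss_tot <- ss_tot + (block[i, j] - gm)^2
  ss_err <- ss_tot - ss_cond - ss_subj
  f <- (ss_cond / (k - 1)) / (ss_err / ((n - 1) * (k - 1)))
  list(F = f, p = pf(f, k - 1, (n - 1) * (k - 1), lower.tail = FALSE))
}

# direct 2x2 counting oracle for sensitivity/specificity of intactness
oracle_confusion <- function(pred, truth) {
  tp <- fn <- tn <- fp <- 0
  for (i in seq_along(pred)) {
    if (is.na(pred[i])) next
    if (truth[i] == "int") {
      if (pred[i] == "positive") tp <- tp + 1 else fn <- fn + 1
    } else {
      if (pred[i] == "negative") tn <- tn + 1 else fp <- fp + 1
    }
  }
  list(sens = tp / (tp + fn), spec = tn / (tn + fp),
       tp = tp, fn = fn, tn = tn, fp = fp)
}

# closed-form pooled-variance two-sample t-test
oracle_t_test <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = t, p = 2 * pt(-abs(t), na + nb - 2))
}

# Spearman rho via explicit mid-rank Pearson formula and t approximation
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  n <- length(x)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  rho <- num / den
  t <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p = 2 * pt(-abs(t), n - 2))
}

# direct noncentral-t power of the two-sided two-sample t-test
oracle_power_two_sample <- function(n, d, alpha = 0.05) {
  df <- 2 * n - 2
  ncp <- d * sqrt(n / 2)
  crit <- qt(1 - alpha / 2, df)
  pt(crit, df, ncp, lower.tail = FALSE) + pt(-crit, df, ncp)
}
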