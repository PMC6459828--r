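#' Coefficient of determination adjusted to the degrees of freedom
#'
#' `1 - (1 - R^2) * (n - 1) / (n - n_params - 1)`, with `R^2` computed
#' against the mean of the observations.
#'
#' @param observed,predicted numeric vectors of equal length.
#' @param n_params number of fitted parameters.
#' @return adjusted R-squared, or `NA` for degenerate (constant) data.
#' @export
adjusted_r2 <- function(observed, predicted, n_params) {
  n <- length(observed)
  stopifnot(length(predicted) == n, n > n_params + 1)
  tss <- sum((observed - mean(observed))^2)
  if (tss == 0) return(NA_real_)
  r2 <- 1 - sum((observed - predicted)^2) / tss
  1 - (1 - r2) * (n - 1) / (n - n_params - 1)
}

# Variable-projection residual sum of squares for S0 * exp(-t/tc):
# for fixed tc the amplitude is linear and solved in closed form.
.monoexp_rss <- function(tc, t, y) {
  x <- exp(-t / tc)
  s0 <- sum(x * y) / sum(x * x)
  sum((y - s0 * x)^2)
}

.fit_monoexp <- function(t, y, bounds = c(1, 5000)) {
  # log-linear seed: slope of log-signal over time
  pos <- y > 0
  tc0 <- NA_real_
  if (sum(pos) >= 2) {
    sl <- stats::cov(t[pos], log(y[pos])) / stats::var(t[pos])
    if (is.finite(sl) && sl < 0) tc0 <- -1 / sl
  }
  lo <- bounds[1]; hi <- bounds[2]
  if (is.finite(tc0)) {
    lo <- max(bounds[1], tc0 / 10)
    hi <- min(bounds[2], tc0 * 10)
    if (lo >= hi) { lo <- bounds[1]; hi <- bounds[2] }
  }
  opt <- stats::optimize(.monoexp_rss, c(lo, hi), t = t, y = y, tol = 1e-9)
  # widen once if the seed bracket pinned the optimum at its edge
  if ((opt$minimum - lo < 1e-6 && lo > bounds[1]) ||
      (hi - opt$minimum < 1e-6 && hi < bounds[2])) {
    opt <- stats::optimize(.monoexp_rss, bounds, t = t, y = y, tol = 1e-9)
  }
  tc <- opt$minimum
  x <- exp(-t / tc)
  s0 <- sum(x * y) / sum(x * x)
  list(tc = tc, s0 = s0, offset = 0, fitted = s0 * x)
}

# RSS of the signed IR model a + b*exp(-ti/t1) for fixed t1 (a, b linear).
.ir_rss <- function(t1, ti, s) {
  x <- exp(-ti / t1)
  fit <- stats::lm.fit(cbind(1, x), s)
  sum(fit$residuals^2)
}

.fit_ir <- function(ti, y, bounds = c(1, 5000)) {
  # polarity restoration: magnitude data have lost the sign of the early
  # (not-yet-recovered) points; try every split index and keep the best fit
  n <- length(y)
  grid <- exp(seq(log(50), log(4000), length.out = 25))
  grid <- grid[grid >= bounds[1] & grid <= bounds[2]]
  best <- list(rss = Inf)
  for (k in 0:(n - 1)) {
    s <- y
    if (k > 0) s[1:k] <- -s[1:k]
    rg <- vapply(grid, .ir_rss, numeric(1), ti = ti, s = s)
    i <- which.min(rg)
    lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
    opt <- stats::optimize(.ir_rss, c(lo, hi), ti = ti, s = s, tol = 1e-9)
    if (opt$objective < best$rss)
      best <- list(rss = opt$objective, t1 = opt$minimum, s = s, k = k)
  }
  x <- exp(-ti / best$t1)
  cf <- stats::lm.fit(cbind(1, x), best$s)$coefficients
  list(tc = best$t1, s0 = -cf[2] / 2, offset = cf[1],
       fitted = abs(cf[1] + cf[2] * x))
}

#' Fit one pixel's relaxation time constant
#'
#' Applies the time-point exclusion rule ([select_times()]), then fits the
#' kind-appropriate model: mono-exponential `S0 exp(-t/Tc)` for T1rho, T2 and
#' T2* (variable projection over the time constant, log-linear seed), or the
#' polarity-restored inversion-recovery model `A + B exp(-TI/T1)` for T1
#' (variable projection with a grid seed over T1 and an exhaustive polarity
#' split). Fit quality is the adjusted R-squared on the retained points; a
#' pixel is valid only if it reaches `r2_threshold` and the time constant is
#' interior to `bounds`. Degenerate signals (all equal, all zero,
#' non-finite) yield an invalid fit rather than an error.
#'
#' @param signal numeric vector aligned to `protocol$time_points`.
#' @param protocol a [qmri_protocol()].
#' @param r2_threshold validity threshold on adjusted R-squared.
#' @param bounds admissible time-constant range in ms.
#' @return list with `time_constant`, `s0`, `offset`, `adjusted_r2`,
#'   `valid`, `n_points_used`.
#' @export
fit_pixel <- function(signal, protocol, r2_threshold = 0.7,
                      bounds = c(1, 5000)) {
  stopifnot(length(signal) == length(protocol$time_points))
  sel <- select_times(protocol)
  y <- as.numeric(signal[sel$index])
  t <- sel$times
  invalid <- list(time_constant = NA_real_, s0 = NA_real_, offset = NA_real_,
                  adjusted_r2 = NA_real_, valid = FALSE,
                  n_points_used = length(t))
  if (any(!is.finite(y)) || all(y == 0) || stats::sd(y) == 0) return(invalid)
  n_par <- if (protocol$kind == "T1") 3L else 2L
  fit <- tryCatch(
    if (protocol$kind == "T1") .fit_ir(t, y, bounds) else .fit_monoexp(t, y, bounds),
    error = function(e) NULL)
  if (is.null(fit) || !is.finite(fit$tc)) return(invalid)
  ar2 <- adjusted_r2(y, fit$fitted, n_par)
  at_bound <- fit$tc <= bounds[1] * (1 + 1e-6) || fit$tc >= bounds[2] * (1 - 1e-6)
  list(time_constant = unname(fit$tc), s0 = unname(fit$s0),
       offset = unname(fit$offset), adjusted_r2 = ar2,
       valid = isTRUE(ar2 >= r2_threshold) && !at_bound && fit$tc > 0,
       n_points_used = length(t))
}

#' Pixel-wise parameter map over a region of interest
#'
#' Runs [fit_pixel()] on every masked pixel of an image series and assembles
#' the spatially resolved map with its validity and fit-quality layers.
#' Identical signal vectors (common in noise-free phantoms) are fitted once
#' and shared.
#'
#' @param series an image series as produced by [render_series()] or
#'   [read_series()]: list with `data` (rows x cols x n_times array) and
#'   `protocol`.
#' @param mask logical matrix of pixels to fit; must be non-empty and match
#'   the image grid.
#' @param r2_threshold,bounds passed to [fit_pixel()].
#' @return object of class `parameter_map`: list with matrices `values`
#'   (ms, `NA` outside mask or where invalid), `valid`, `r2`, plus `kind`,
#'   `displacement`, `sample_id`, `pixel_spacing`.
#' @export
fit_map <- function(series, mask, r2_threshold = 0.7, bounds = c(1, 5000)) {
  d <- dim(series$data)
  if (!is.matrix(mask) || !all(dim(mask) == d[1:2]))
    stop("mask must be a matrix matching the image grid")
  idx <- which(mask)
  if (length(idx) == 0) stop("empty mask")
  ntp <- d[3]
  sig <- matrix(series$data, nrow = d[1] * d[2], ncol = ntp)[idx, , drop = FALSE]
  keys <- apply(sig, 1, paste, collapse = ",")
  first <- !duplicated(keys)
  fits <- apply(sig[first, , drop = FALSE], 1, fit_pixel,
                protocol = series$protocol, r2_threshold = r2_threshold,
                bounds = bounds)
  fits <- fits[match(keys, keys[first])]
  values <- valid <- r2 <- matrix(NA, d[1], d[2])
  tc <- vapply(fits, function(f) f$time_constant, numeric(1))
  vl <- vapply(fits, function(f) f$valid, logical(1))
  values[idx] <- ifelse(vl, tc, NA_real_)
  valid[idx] <- vl
  r2[idx] <- vapply(fits, function(f) f$adjusted_r2, numeric(1))
  structure(list(values = values, valid = valid, r2 = r2,
                 kind = series$protocol$kind,
                 displacement = series$displacement,
                 sample_id = series$sample_id,
                 pixel_spacing = series$protocol$pixel_spacing),
            class = "parameter_map")
}

#' @export
print.parameter_map <- function(x, ...) {
  nv <- sum(x$valid, na.rm = TRUE)
  cat(sprintf("<parameter_map %s, %s: %d valid pixels, mean %.1f ms>\n",
              x$kind, x$displacement %||% "?", nv,
              mean(x$values, na.rm = TRUE)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
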