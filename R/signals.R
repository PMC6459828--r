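#' Mono-exponential decay signal
#'
#' `S(t) = S0 * exp(-t / Tc)` — the forward model for T1rho (t = spin-lock
#' duration), T2 and T2* (t = echo time).
#'
#' @param t time in ms (vectorised).
#' @param s0 signal amplitude at t = 0.
#' @param tc time constant in ms, > 0.
#' @export
signal_monoexp <- function(t, s0, tc) {
  if (any(tc <= 0)) stop("time constant must be positive")
  s0 * exp(-t / tc)
}

#' Magnitude inversion-recovery signal
#'
#' `|S0 * (1 - 2 exp(-TI/T1) + exp(-TR/T1))|` — inversion recovery with a
#' finite-TR recovery term, taken in magnitude as reconstructed MR images
#' carry no polarity.
#'
#' @param ti inversion time in ms (vectorised).
#' @param s0 equilibrium amplitude.
#' @param t1 longitudinal relaxation time in ms, > 0.
#' @param tr repetition time in ms.
#' @export
signal_ir <- function(ti, s0, t1, tr) {
  if (any(t1 <= 0)) stop("T1 must be positive")
  abs(s0 * (1 - 2 * exp(-ti / t1) + exp(-tr / t1)))
}

#' Apply Rician noise to a magnitude image
#'
#' Magnitude MR noise: both quadrature channels receive independent Gaussian
#' noise of scale `sigma`, and the magnitude is retained. For zero underlying
#' signal this reduces to a Rayleigh distribution with mean
#' `sigma * sqrt(pi / 2)`.
#'
#' @param s array of noise-free magnitude values (any shape).
#' @param sigma Gaussian channel noise SD; `0` returns `s` unchanged.
#' @return array of the same shape.
#' @export
add_rician <- function(s, sigma) {
  if (sigma < 0) stop("sigma must be non-negative")
  if (sigma == 0) return(s)
  n <- length(s)
  out <- sqrt((s + stats::rnorm(n, sd = sigma))^2 + stats::rnorm(n, sd = sigma)^2)
  if (!is.null(dim(s))) dim(out) <- dim(s)
  out
}
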