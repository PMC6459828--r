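#' Acquisition protocol for one qMRI mapping sequence
#'
#' A protocol bundles the sequence kind with the ordered sampling times of
#' its relaxation dimension (inversion times for T1, spin-lock durations for
#' T1rho, echo times for T2 and T2*), the repetition time, and the in-plane
#' geometry of the reconstructed image.
#'
#' @param kind one of `"T1"` (inversion recovery), `"T1rho"` (spin-lock),
#'   `"T2"` (multi-spin echo), `"T2star"` (multi-gradient echo).
#' @param time_points numeric vector of sampling times in ms, strictly
#'   increasing and non-negative.
#' @param repetition_time repetition time TR in ms.
#' @param fov_mm in-plane field of view (square) in mm.
#' @param grid integer vector `c(rows, cols)` of the reconstruction matrix.
#' @return an object of class `qmri_protocol`.
#' @export
qmri_protocol <- function(kind, time_points, repetition_time,
                          fov_mm = 30, grid = c(80L, 80L)) {
  kind <- match.arg(kind, c("T1", "T1rho", "T2", "T2star"))
  time_points <- as.numeric(time_points)
  if (any(!is.finite(time_points)) || any(time_points < 0))
    stop("time_points must be finite and non-negative")
  if (is.unsorted(time_points, strictly = TRUE))
    stop("time_points must be strictly increasing")
  structure(list(
    kind = kind,
    time_points = time_points,
    repetition_time = as.numeric(repetition_time),
    fov_mm = as.numeric(fov_mm),
    grid = as.integer(grid),
    pixel_spacing = as.numeric(fov_mm) / as.integer(grid)[1]
  ), class = "qmri_protocol")
}

#' @export
print.qmri_protocol <- function(x, ...) {
  cat(sprintf("<qmri_protocol %s: %d time points (%.2f-%.2f ms), TR %g ms, FOV %g mm, %dx%d>\n",
              x$kind, length(x$time_points), min(x$time_points),
              max(x$time_points), x$repetition_time, x$fov_mm,
              x$grid[1], x$grid[2]))
  invisible(x)
}

#' Standard mapping protocols of the loading experiment
#'
#' Returns the four acquisition protocols used throughout the pipeline:
#' inversion-recovery T1 (7 inversion times, TR 3000 ms), spin-lock T1rho
#' (5 spin-lock durations including 0 ms), multi-spin-echo T2 (8 echoes at
#' multiples of 9.01 ms) and multi-gradient-echo T2* (10 echoes
#' 2.84 + n * 4.54 ms, n = 0..9). All four image a 30 mm field of view
#' reconstructed at 80 x 80 (0.375 mm pixels).
#'
#' @return named list of [qmri_protocol()] objects
#'   (`T1`, `T1rho`, `T2`, `T2star`).
#' @export
make_protocols <- function() {
  list(
    T1 = qmri_protocol("T1", c(150, 300, 500, 800, 1000, 1300, 1500),
                       repetition_time = 3000),
    T1rho = qmri_protocol("T1rho", c(0, 10, 20, 30, 40),
                          repetition_time = 30),
    T2 = qmri_protocol("T2", 9.01 * (1:8), repetition_time = 1000),
    T2star = qmri_protocol("T2star", 2.84 + 4.54 * (0:9),
                           repetition_time = 700)
  )
}

#' Time-point exclusion rule for curve fitting
#'
#' For T1 and T1rho all acquired points enter the fit. For T2 and T2* the
#' first echo is dropped (stimulated-echo / fitting inaccuracies) together
#' with any echo time above 60 ms (insufficient signal-to-noise). At least
#' three points must survive, otherwise fitting is refused.
#'
#' @param protocol a [qmri_protocol()].
#' @return list with `times` (retained time points, ms) and `index`
#'   (positions within `protocol$time_points`).
#' @export
select_times <- function(protocol) {
  stopifnot(inherits(protocol, "qmri_protocol"))
  tp <- protocol$time_points
  idx <- seq_along(tp)
  if (protocol$kind %in% c("T2", "T2star")) {
    keep <- idx != 1L & tp <= 60
    idx <- idx[keep]
  }
  if (length(idx) < 3L)
    stop("fewer than 3 time points retained after exclusion; fitting refused")
  list(times = tp[idx], index = idx)
}
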