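#' @keywords internal
"_PACKAGE"

# canonical labels used throughout the pipeline
.DISP <- c("d0", "d2.5", "d5.0")
.PARAMS <- c("T1", "T1rho", "T2", "T2star")
.ZONES <- c("sf", "dp")
.MSS_CAPS <- c(structure = 6L, cellularity = 3L, proteoglycan = 4L, tidemark = 1L)

#' Displacement position labels
#'
#' The three loading positions of the serial experiment: unloaded (`d0`),
#' 2.5 mm (`d2.5`) and 5.0 mm (`d5.0`) tibial displacement.
#' @return character vector of length 3.
#' @export
displacements <- function() .DISP

#' qMRI parameter kinds
#' @return `c("T1", "T1rho", "T2", "T2star")`.
#' @export
qmri_parameters <- function() .PARAMS

#' Default zonal group distributions and loading-shift factors
#'
#' Per (parameter, zone, group) the unloaded mean and SD and the cohort mean
#' values at the two loading positions, from which multiplicative loading
#' shift factors `f2.5 = mean(d2.5)/mean(d0)` and `f5.0 = mean(d5.0)/mean(d0)`
#' are derived. Values are the published zonal summaries of 27 intact and 22
#' early-degenerative human cartilage samples (ms).
#'
#' @return data.frame with columns `parameter`, `zone`, `group`, `mean_d0`,
#'   `sd_d0`, `mean_d2.5`, `mean_d5.0`, `f2.5`, `f5.0`.
#' @export
default_group_params <- function() {
  df <- rbind(
    # parameter zone group  mean_d0 sd_d0  mean_d2.5 mean_d5.0
    data.frame(parameter = "T1",     zone = "sf", group = "int", mean_d0 = 784.1, sd_d0 = 133.8, mean_d2.5 = 685.4, mean_d5.0 = 640.0),
    data.frame(parameter = "T1",     zone = "dp", group = "int", mean_d0 = 684.4, sd_d0 = 121.2, mean_d2.5 = 663.9, mean_d5.0 = 642.2),
    data.frame(parameter = "T1rho",  zone = "sf", group = "int", mean_d0 = 108.5, sd_d0 = 18.7,  mean_d2.5 = 107.0, mean_d5.0 = 104.0),
    data.frame(parameter = "T1rho",  zone = "dp", group = "int", mean_d0 = 94.9,  sd_d0 = 18.1,  mean_d2.5 = 105.5, mean_d5.0 = 108.1),
    data.frame(parameter = "T2",     zone = "sf", group = "int", mean_d0 = 46.4,  sd_d0 = 7.0,   mean_d2.5 = 45.7,  mean_d5.0 = 41.2),
    data.frame(parameter = "T2",     zone = "dp", group = "int", mean_d0 = 35.1,  sd_d0 = 5.8,   mean_d2.5 = 38.8,  mean_d5.0 = 37.9),
    data.frame(parameter = "T2star", zone = "sf", group = "int", mean_d0 = 23.9,  sd_d0 = 5.2,   mean_d2.5 = 24.6,  mean_d5.0 = 23.8),
    data.frame(parameter = "T2star", zone = "dp", group = "int", mean_d0 = 19.9,  sd_d0 = 4.3,   mean_d2.5 = 20.2,  mean_d5.0 = 20.1),
    data.frame(parameter = "T1",     zone = "sf", group = "deg", mean_d0 = 788.3, sd_d0 = 100.3, mean_d2.5 = 716.0, mean_d5.0 = 684.6),
    data.frame(parameter = "T1",     zone = "dp", group = "deg", mean_d0 = 763.3, sd_d0 = 123.4, mean_d2.5 = 740.5, mean_d5.0 = 726.2),
    data.frame(parameter = "T1rho",  zone = "sf", group = "deg", mean_d0 = 103.7, sd_d0 = 18.2,  mean_d2.5 = 105.7, mean_d5.0 = 112.1),
    data.frame(parameter = "T1rho",  zone = "dp", group = "deg", mean_d0 = 93.0,  sd_d0 = 17.7,  mean_d2.5 = 112.0, mean_d5.0 = 114.2),
    data.frame(parameter = "T2",     zone = "sf", group = "deg", mean_d0 = 46.3,  sd_d0 = 9.9,   mean_d2.5 = 46.0,  mean_d5.0 = 43.8),
    data.frame(parameter = "T2",     zone = "dp", group = "deg", mean_d0 = 39.9,  sd_d0 = 7.3,   mean_d2.5 = 42.0,  mean_d5.0 = 45.4),
    data.frame(parameter = "T2star", zone = "sf", group = "deg", mean_d0 = 22.7,  sd_d0 = 5.1,   mean_d2.5 = 25.1,  mean_d5.0 = 25.1),
    data.frame(parameter = "T2star", zone = "dp", group = "deg", mean_d0 = 21.7,  sd_d0 = 6.0,   mean_d2.5 = 20.0,  mean_d5.0 = 22.1)
  )
  df$`f2.5` <- df$`mean_d2.5` / df$mean_d0
  df$`f5.0` <- df$`mean_d5.0` / df$mean_d0
  df
}

#' Cohort generator configuration
#'
#' All tunable knobs of the synthetic cohort: group sizes, the zonal group
#' distributions and loading-shift factors, geometry and its loading
#' response, image noise, per-sample shift variability, biomechanics, and
#' the seed that makes a cohort fully reproducible.
#'
#' @param n_int,n_deg number of intact / early-degenerative samples.
#' @param params group distribution table, see [default_group_params()].
#' @param height_mm,width_mm unloaded disc geometry (3 mm standard cutting
#'   thickness, 8 mm biopsy-punch diameter).
#' @param height_factors named mean height scaling at the loaded positions;
#'   defaults reproduce the observed cohort-mean height changes of -6.1%
#'   (2.5 mm) and -15.6% (5.0 mm).
#' @param shift_sd_log per-sample log-scale SD of the multiplicative loading
#'   shift (within-subject response variability); 0 makes shifts exact.
#' @param s0 proton-density reference amplitude of cartilage.
#' @param noise_sigma Rician channel noise SD; the default `s0 / 50` gives a
#'   disc SNR of about 50 at full signal.
#' @param ym Young's modulus truth distribution per group (MPa).
#' @param curve_noise_sd additive stress noise on synthetic stress-strain
#'   curves (MPa).
#' @param seed integer RNG seed; a fixed seed yields a byte-identical cohort.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_int = 27, n_deg = 22,
                          params = default_group_params(),
                          height_mm = 3, width_mm = 8,
                          height_factors = c("d2.5" = 0.939, "d5.0" = 0.844),
                          shift_sd_log = 0.12,
                          s0 = 1000, noise_sigma = s0 / 50,
                          ym = list(int = c(mean = 0.55, sd = 0.31),
                                    deg = c(mean = 0.35, sd = 0.34)),
                          curve_noise_sd = 0.005,
                          seed = 1L) {
  stopifnot(n_int >= 0, n_deg >= 0, all(params$sd_d0 >= 0),
            shift_sd_log >= 0, noise_sigma >= 0, height_mm > 0, width_mm > 0,
            all(height_factors > 0), all(height_factors <= 1))
  structure(list(n_int = as.integer(n_int), n_deg = as.integer(n_deg),
                 params = params, height_mm = height_mm, width_mm = width_mm,
                 height_factors = height_factors, shift_sd_log = shift_sd_log,
                 s0 = s0, noise_sigma = noise_sigma, ym = ym,
                 curve_noise_sd = curve_noise_sd, seed = as.integer(seed)),
            class = "cohort_config")
}

#' Zero-variability configuration
#'
#' A [cohort_config()] with all SDs, shift variability and image noise set to
#' zero: every sample equals the configured group means and the full pipeline
#' must recover the configuration exactly.
#' @param ... overrides passed on to [cohort_config()].
#' @export
zero_noise_config <- function(...) {
  p <- default_group_params()
  p$sd_d0 <- 0
  cohort_config(params = p, shift_sd_log = 0, noise_sigma = 0,
                ym = list(int = c(mean = 0.55, sd = 0), deg = c(mean = 0.35, sd = 0)),
                curve_noise_sd = 0, ...)
}

# positive truncated normal draw (rejection, with a floor fallback)
.rtruncnorm_pos <- function(n, mean, sd, floor = 1e-3) {
  if (sd == 0) return(rep(mean, n))
  out <- stats::rnorm(n, mean, sd)
  for (i in seq_len(50)) {
    bad <- out <= floor
    if (!any(bad)) break
    out[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  pmax(out, floor)
}

# draw Mankin subscores whose sum falls in the group's range by allocating
# the target sum unit-by-unit across subscores with remaining capacity
.draw_mss <- function(group) {
  target <- if (group == "int") sample(0:4, 1) else sample(5:8, 1)
  sub <- stats::setNames(integer(4), names(.MSS_CAPS))
  for (i in seq_len(target)) {
    open <- names(sub)[sub < .MSS_CAPS]
    pick <- if (length(open) == 1) open else sample(open, 1)
    sub[pick] <- sub[pick] + 1L
  }
  sub
}

#' Draw one ground-truth phantom
#'
#' Samples zonal true relaxation times at the unloaded position from the
#' configured group distributions (truncated at positivity), applies the
#' multiplicative loading-shift factors with per-sample log-normal
#' variability (`shift_sd_log`) to obtain the loaded truths, and draws
#' Mankin subscores consistent with the group's sum range and a positive
#' true Young's modulus.
#'
#' @param config a [cohort_config()].
#' @param group `"int"` or `"deg"`.
#' @param sample_id identifier stored in the phantom.
#' @return object of class `qmri_phantom` with `true_fields`, a
#'   parameter x zone x displacement array in ms.
#' @export
sample_truth <- function(config, group, sample_id = "S01") {
  group <- match.arg(group, c("int", "deg"))
  tf <- array(NA_real_, dim = c(4, 2, 3),
              dimnames = list(.PARAMS, .ZONES, .DISP))
  p <- config$params
  for (par in .PARAMS) for (zn in .ZONES) {
    row <- p[p$parameter == par & p$zone == zn & p$group == group, ]
    if (nrow(row) != 1) stop("config distributions missing for ", par, "/", zn)
    base <- .rtruncnorm_pos(1, row$mean_d0, row$sd_d0)
    e <- if (config$shift_sd_log > 0)
      exp(stats::rnorm(2, 0, config$shift_sd_log)) else c(1, 1)
    tf[par, zn, "d0"]   <- base
    tf[par, zn, "d2.5"] <- base * row$`f2.5` * e[1]
    tf[par, zn, "d5.0"] <- base * row$`f5.0` * e[2]
  }
  sub <- .draw_mss(group)
  ymp <- config$ym[[group]]
  structure(list(
    sample_id = sample_id, group = group,
    mss_subscores = sub, mss = sum(sub),
    width_mm = config$width_mm, height_mm = config$height_mm,
    height_factors = config$height_factors,
    true_fields = tf,
    proton_density = config$s0, noise_sigma = config$noise_sigma,
    young_modulus_true = .rtruncnorm_pos(1, ymp["mean"], ymp["sd"], floor = 0.01),
    displacement = "d0"
  ), class = "qmri_phantom")
}

#' Deform a phantom to a loading position
#'
#' Scales the disc height by the configured mean fractional height change of
#' the displacement (width unchanged) and marks the phantom as being at that
#' position, so that rendering and truth lookups use the loaded values.
#' `d0` is the identity.
#'
#' @param truth a `qmri_phantom`.
#' @param displacement one of `displacements()`.
#' @export
deform <- function(truth, displacement) {
  displacement <- match.arg(displacement, .DISP)
  out <- truth
  if (displacement != "d0")
    out$height_mm <- truth$height_mm * truth$height_factors[[displacement]]
  out$displacement <- displacement
  out
}

#' Stadium-shaped disc mask
#'
#' Mid-coronal cross-section of the cylindrical sample: a rectangle with
#' semicircular ends (width along columns, height along rows), rasterised on
#' the protocol grid by pixel-centre inclusion.
#'
#' @param width_mm,height_mm disc dimensions.
#' @param grid `c(rows, cols)`.
#' @param spacing pixel spacing in mm.
#' @return logical matrix.
#' @export
disc_mask <- function(width_mm, height_mm, grid = c(80L, 80L), spacing = 0.375) {
  rows <- grid[1]; cols <- grid[2]
  x <- (seq_len(cols) - (cols + 1) / 2) * spacing
  y <- (seq_len(rows) - (rows + 1) / 2) * spacing
  hw <- max(width_mm - height_mm, 0) / 2   # half-length of the straight segment
  r <- height_mm / 2
  dx <- pmax(abs(matrix(x, rows, cols, byrow = TRUE)) - hw, 0)
  dy <- matrix(y, rows, cols)
  dx^2 + dy^2 <= r^2
}

# silicone condyle layer surrounding the disc (hypointense in all contrasts)
.silicone_mask <- function(width_mm, height_mm, grid, spacing) {
  disc_mask(width_mm + 4, height_mm + 3, grid, spacing) &
    !disc_mask(width_mm, height_mm, grid, spacing)
}

.SILICONE_TC <- c(T1 = 250, T1rho = 40, T2 = 4, T2star = 3)

# evaluate the kind-appropriate forward model
.forward_signal <- function(protocol, s0, tc) {
  if (protocol$kind == "T1")
    signal_ir(protocol$time_points, s0, tc, protocol$repetition_time)
  else
    signal_monoexp(protocol$time_points, s0, tc)
}

#' Render a serial image stack for one phantom and protocol
#'
#' Deforms the phantom to the requested displacement, rasterises the disc on
#' the protocol grid, assigns each zone its true relaxation time for the
#' displacement, evaluates the sequence's forward model at every time point
#' (disc at full proton density, a surrounding silicone layer hypointense at
#' 30% amplitude with short time constants, background at zero), and applies
#' independent Rician noise to every image.
#'
#' @param truth a `qmri_phantom`.
#' @param protocol a [qmri_protocol()].
#' @param displacement one of `displacements()`.
#' @param surface_side which image side the articular surface faces
#'   (`"bottom"` default: the sample surface points at the tibia).
#' @return an image-series list: `data` (rows x cols x n_times), ground-truth
#'   `mask` and `zone` label matrix (0 background, 1 sf, 2 dp), `protocol`,
#'   `displacement`, `sample_id`, `pixel_spacing`.
#' @export
render_series <- function(truth, protocol, displacement,
                          surface_side = "bottom") {
  stopifnot(inherits(protocol, "qmri_protocol"))
  ph <- deform(truth, displacement)
  grid <- protocol$grid; sp <- protocol$pixel_spacing
  mask <- disc_mask(ph$width_mm, ph$height_mm, grid, sp)
  if (!any(mask)) stop("deformed disc rasterises to an empty mask")
  zones <- .split_columns(mask, surface_side)
  zone <- matrix(0L, grid[1], grid[2])
  zone[zones$sf] <- 1L
  zone[zones$dp] <- 2L
  sil <- .silicone_mask(ph$width_mm, ph$height_mm, grid, sp)
  tc_true <- ph$true_fields[protocol$kind, , displacement]
  ntp <- length(protocol$time_points)
  data <- array(0, dim = c(grid[1], grid[2], ntp))
  sig_sf <- .forward_signal(protocol, ph$proton_density, tc_true[["sf"]])
  sig_dp <- .forward_signal(protocol, ph$proton_density, tc_true[["dp"]])
  sig_si <- .forward_signal(protocol, 0.3 * ph$proton_density,
                            .SILICONE_TC[[protocol$kind]])
  for (k in seq_len(ntp)) {
    frame <- matrix(0, grid[1], grid[2])
    frame[sil] <- sig_si[k]
    frame[zone == 1L] <- sig_sf[k]
    frame[zone == 2L] <- sig_dp[k]
    data[, , k] <- frame
  }
  if (ph$noise_sigma > 0) data <- add_rician(data, ph$noise_sigma)
  list(data = data, mask = mask, zone = zone, protocol = protocol,
       displacement = displacement, sample_id = ph$sample_id,
       pixel_spacing = sp)
}
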