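#' Synthetic unconfined-compression stress-strain curve
#'
#' Linear elastic response `stress = E * strain` sampled on a strictly
#' increasing strain grid up to the 21% protocol maximum, with additive
#' Gaussian stress noise (clamped at zero: measured force is non-negative).
#'
#' @param e_true true Young's modulus in MPa, > 0.
#' @param noise_sd additive stress noise SD in MPa.
#' @param n_points grid size (default 85: a 0.25% strain step whose grid
#'   contains the 10% and 20% window edges exactly).
#' @return object of class `stress_strain`: list with `strain` (fractional)
#'   and `stress` (MPa).
#' @export
synth_stress_strain <- function(e_true, noise_sd = 0, n_points = 85) {
  if (e_true <= 0) stop("E_true must be positive")
  strain <- seq(0, 0.21, length.out = n_points)
  stress <- e_true * strain
  if (noise_sd > 0) stress <- pmax(0, stress + stats::rnorm(n_points, 0, noise_sd))
  structure(list(strain = strain, stress = stress), class = "stress_strain")
}

#' Generate a full synthetic cohort
#'
#' Draws `n_int + n_deg` ground-truth phantoms under the configuration's
#' seed, a stress-strain curve per sample and - optionally - the complete
#' serial image data: four mapping sequences at three displacement positions
#' per sample. A fixed seed makes the whole bundle reproducible.
#'
#' @param config a [cohort_config()].
#' @param render if `TRUE`, render all image series (4 sequences x 3
#'   displacements per sample); if `FALSE`, only truths, curves and metadata
#'   are produced (fast path for statistical simulation).
#' @return object of class `qmri_cohort`: list with `phantoms`, `curves`,
#'   `series` (nested `[[sample]][[kind]][[displacement]]`, or `NULL`),
#'   `metadata` data.frame and the `config`.
#' @export
generate_cohort <- function(config, render = TRUE) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  groups <- c(rep("int", config$n_int), rep("deg", config$n_deg))
  n <- length(groups)
  ids <- sprintf("S%03d", seq_len(n))
  protocols <- make_protocols()
  phantoms <- curves <- series <- stats::setNames(vector("list", n), ids)
  for (i in seq_len(n)) {
    ph <- sample_truth(config, groups[i], ids[i])
    phantoms[[i]] <- ph
    curves[[i]] <- synth_stress_strain(ph$young_modulus_true,
                                       config$curve_noise_sd)
    if (render) {
      series[[i]] <- lapply(protocols, function(pr)
        stats::setNames(lapply(.DISP, function(d)
          render_series(ph, pr, d)), .DISP))
    }
  }
  metadata <- if (n == 0) {
    data.frame(sample_id = character(), group = character(),
               mss_structure = integer(), mss_cellularity = integer(),
               mss_proteoglycan = integer(), mss_tidemark = integer(),
               mss = integer(), ym_true = numeric(), seed = integer())
  } else {
    data.frame(
      sample_id = ids, group = groups,
      mss_structure = vapply(phantoms, function(p) p$mss_subscores[["structure"]], integer(1)),
      mss_cellularity = vapply(phantoms, function(p) p$mss_subscores[["cellularity"]], integer(1)),
      mss_proteoglycan = vapply(phantoms, function(p) p$mss_subscores[["proteoglycan"]], integer(1)),
      mss_tidemark = vapply(phantoms, function(p) p$mss_subscores[["tidemark"]], integer(1)),
      mss = vapply(phantoms, function(p) p$mss, integer(1)),
      ym_true = vapply(phantoms, function(p) p$young_modulus_true, numeric(1)),
      seed = config$seed)
  }
  structure(list(phantoms = phantoms, curves = curves,
                 series = if (render) series else NULL,
                 metadata = metadata, config = config),
            class = "qmri_cohort")
}

#' @export
print.qmri_cohort <- function(x, ...) {
  cat(sprintf("<qmri_cohort: %d int + %d deg samples, seed %d, %s image data>\n",
              x$config$n_int, x$config$n_deg, x$config$seed,
              if (is.null(x$series)) "without" else "with"))
  invisible(x)
}

#' Tidy table of ground-truth zonal values
#'
#' One row per (sample, parameter, zone, displacement) with the phantom's
#' true relaxation time. The entire-sample (ECS) truth is the mean of the two
#' zone truths (equal-zone partition).
#'
#' @param cohort a `qmri_cohort`.
#' @return tidy data.frame: `sample_id`, `group`, `mss`, `parameter`,
#'   `zone`, `displacement`, `value`.
#' @export
cohort_truth_table <- function(cohort) {
  stopifnot(inherits(cohort, "qmri_cohort"))
  rows <- lapply(cohort$phantoms, function(ph) {
    tf <- ph$true_fields
    grid <- expand.grid(parameter = .PARAMS, zone = c(.ZONES, "ECS"),
                        displacement = .DISP, stringsAsFactors = FALSE)
    grid$value <- mapply(function(p, z, d)
      if (z == "ECS") mean(tf[p, , d]) else tf[p, z, d],
      grid$parameter, grid$zone, grid$displacement)
    cbind(sample_id = ph$sample_id, group = ph$group, mss = ph$mss, grid,
          row.names = NULL)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
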