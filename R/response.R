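#' Relative change of a loaded value versus the unloaded baseline
#'
#' `((v_loaded / v_unloaded) - 1) * 100` in percent; this is the per-sample
#' loading-response biomarker (Delta2.5, Delta5.0). Undefined (NA) for a
#' missing or non-positive baseline.
#'
#' @param v_loaded,v_unloaded values in the same units (vectorised).
#' @return percent change.
#' @export
relative_change <- function(v_loaded, v_unloaded) {
  out <- ifelse(!is.na(v_unloaded) & v_unloaded > 0,
                (v_loaded / v_unloaded - 1) * 100, NA_real_)
  unname(out)
}

#' Young's modulus by tangent fit over 10-20% strain
#'
#' Ordinary least-squares slope (with intercept) of stress on strain,
#' restricted to the strain window \[0.10, 0.20\].
#'
#' @param curve a `stress_strain` object (or list with `strain`, `stress`).
#' @return modulus in MPa.
#' @export
young_modulus <- function(curve) {
  sel <- curve$strain >= 0.10 & curve$strain <= 0.20
  if (sum(sel) < 3) stop("fewer than 3 points in the 10-20% strain window")
  x <- curve$strain[sel]; y <- curve$stress[sel]
  unname(stats::cov(x, y) / stats::var(x))
}

#' Measured zonal means of a rendered cohort
#'
#' The image-analysis pipeline: for every sample, displacement and sequence,
#' the ground-truth disc mask is boundary-eroded and split into equal zones,
#' the parameter map is fitted pixel-wise over the eroded mask, and the zonal
#' means, pixel counts and the caliper geometry are assembled into a tidy
#' per-sample table.
#'
#' @param cohort a rendered `qmri_cohort` (see [generate_cohort()]).
#' @param r2_threshold fit-quality threshold forwarded to [fit_map()].
#' @return tidy data.frame, one row per (sample, parameter, zone,
#'   displacement): `sample_id`, `group`, `mss`, `displacement`, `parameter`,
#'   `zone`, `mean`, `n_valid`, `height_mm`, `width_mm`, `young_modulus`.
#' @export
pipeline_cohort_table <- function(cohort, r2_threshold = 0.7) {
  stopifnot(inherits(cohort, "qmri_cohort"))
  if (is.null(cohort$series))
    stop("cohort was generated without image data (render = FALSE)")
  rows <- list()
  for (id in names(cohort$phantoms)) {
    ph <- cohort$phantoms[[id]]
    ym <- young_modulus(cohort$curves[[id]])
    for (d in .DISP) {
      mask0 <- cohort$series[[id]][[1]][[d]]$mask
      sp <- cohort$series[[id]][[1]][[d]]$pixel_spacing
      geom <- caliper(mask0, sp)
      roi <- split_zones(erode_boundary(mask0))
      for (par in .PARAMS) {
        ser <- cohort$series[[id]][[par]][[d]]
        map <- fit_map(ser, roi$ecs_mask, r2_threshold = r2_threshold)
        zs <- zonal_stats(map, roi)
        rows[[length(rows) + 1]] <- data.frame(
          sample_id = id, group = ph$group, mss = ph$mss,
          displacement = d, parameter = par, zone = zs$zone,
          mean = zs$mean, n_valid = zs$n_valid,
          height_mm = geom[["height_mm"]], width_mm = geom[["width_mm"]],
          young_modulus = ym)
      }
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Per-sample loading-response table
#'
#' Reshapes a tidy zonal table (measured via [pipeline_cohort_table()] or
#' ground truth via [cohort_truth_table()]) to one row per (sample,
#' parameter, zone) with the three displacement values and the per-sample
#' relative changes `delta2.5` and `delta5.0` in percent.
#'
#' @param table tidy table with columns `sample_id`, `group`, `parameter`,
#'   `zone`, `displacement` and a value column.
#' @param value name of the value column (`"mean"` or `"value"`).
#' @return wide data.frame with columns `d0`, `d2.5`, `d5.0`, `delta2.5`,
#'   `delta5.0`.
#' @export
loading_response_table <- function(table, value = if ("mean" %in% names(table)) "mean" else "value") {
  wide <- stats::reshape(
    table[, c("sample_id", "group", "parameter", "zone", "displacement", value)],
    idvar = c("sample_id", "group", "parameter", "zone"),
    timevar = "displacement", direction = "wide")
  names(wide) <- sub(paste0("^", value, "\\."), "", names(wide))
  wide$`delta2.5` <- relative_change(wide$`d2.5`, wide$d0)
  wide$`delta5.0` <- relative_change(wide$`d5.0`, wide$d0)
  rownames(wide) <- NULL
  wide
}

#' Assemble a cohort table from per-sample records
#'
#' Binds per-sample record data.frames into one tidy cohort table, refusing
#' duplicate sample identifiers. An empty input yields an empty table with
#' the full header.
#'
#' @param records list of data.frames sharing a schema that includes
#'   `sample_id`.
#' @export
build_cohort_table <- function(records) {
  if (length(records) == 0)
    return(data.frame(sample_id = character(), group = character(),
                      mss = integer(), displacement = character(),
                      parameter = character(), zone = character(),
                      mean = numeric()))
  ids <- vapply(records, function(r) as.character(r$sample_id[1]), character(1))
  if (anyDuplicated(ids)) stop("duplicate sample_id in records")
  do.call(rbind, c(records, list(make.row.names = FALSE)))
}
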