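# per-column equal split of a mask into superficial and deep halves;
# odd columns give the extra pixel to the deep zone (deterministic tie-break)
.split_columns <- function(mask, surface_side = c("bottom", "top")) {
  surface_side <- match.arg(surface_side)
  sf <- dp <- mask & FALSE
  for (j in seq_len(ncol(mask))) {
    rows <- which(mask[, j])
    k <- length(rows)
    if (k == 0) next
    nsf <- k %/% 2L
    if (surface_side == "bottom") {       # large row index = near surface
      sf[utils::tail(rows, nsf), j] <- TRUE
      dp[utils::head(rows, k - nsf), j] <- TRUE
    } else {
      sf[utils::head(rows, nsf), j] <- TRUE
      dp[utils::tail(rows, k - nsf), j] <- TRUE
    }
  }
  list(sf = sf, dp = dp)
}

#' Exclude boundary pixels in the depth direction
#'
#' Removes the top-most and bottom-most masked pixel of every column
#' (depth-direction erosion only), mirroring the exclusion of surface and
#' bottom boundary pixels to prevent partial-volume contamination. Columns
#' with two or fewer pixels vanish entirely.
#'
#' @param mask logical matrix, non-empty.
#' @return logical matrix, a subset of `mask`.
#' @export
erode_boundary <- function(mask) {
  if (!any(mask)) stop("empty mask")
  out <- mask
  for (j in seq_len(ncol(mask))) {
    rows <- which(mask[, j])
    if (length(rows) > 0) out[range(rows), j] <- FALSE
  }
  if (!any(out)) stop("mask too thin: nothing survives boundary erosion")
  out
}

#' Partition a sample mask into equal superficial and deep zones
#'
#' Per column, the half of the masked pixels nearer the articular surface
#' becomes the superficial (sf) zone and the remainder the deep (dp) zone;
#' odd pixel counts assign the extra pixel to the deep zone. The union of the
#' two zones is exactly the input mask.
#'
#' @param mask logical matrix (typically already boundary-eroded), non-empty.
#' @param surface_side `"bottom"` (default) or `"top"`: image side the
#'   articular surface faces.
#' @return object of class `sample_roi`: list with logical matrices
#'   `ecs_mask`, `sf_mask`, `dp_mask` and the `surface_side`.
#' @export
split_zones <- function(mask, surface_side = "bottom") {
  if (!any(mask)) stop("empty mask")
  z <- .split_columns(mask, surface_side)
  structure(list(ecs_mask = mask, sf_mask = z$sf, dp_mask = z$dp,
                 surface_side = surface_side),
            class = "sample_roi")
}

#' Digital-caliper sample geometry
#'
#' Height is the masked extent (pixel count times spacing) of the central
#' column, width that of the central row; the centre is the midpoint of the
#' mask's bounding box.
#'
#' @param mask logical matrix, non-empty.
#' @param pixel_spacing pixel size in mm.
#' @return named numeric `c(height_mm, width_mm)`.
#' @export
caliper <- function(mask, pixel_spacing) {
  if (!any(mask)) stop("empty mask")
  rows <- which(rowSums(mask) > 0)
  cols <- which(colSums(mask) > 0)
  rc <- round((min(rows) + max(rows)) / 2)
  cc <- round((min(cols) + max(cols)) / 2)
  c(height_mm = sum(mask[, cc]) * pixel_spacing,
    width_mm = sum(mask[rc, ]) * pixel_spacing)
}

#' Zonal summary of a parameter map
#'
#' Mean over valid pixels, valid-pixel count and invalid fraction for the
#' entire cartilage sample (ECS) and its two zones. Zones without a single
#' valid pixel get an `NA` mean and are flagged rather than raising.
#'
#' @param map a `parameter_map` from [fit_map()].
#' @param roi a `sample_roi` from [split_zones()].
#' @return data.frame with one row per zone (`ECS`, `sf`, `dp`): `mean`,
#'   `n_valid`, `n_total`, `frac_invalid`, `flagged`.
#' @export
zonal_stats <- function(map, roi) {
  stopifnot(inherits(map, "parameter_map"), inherits(roi, "sample_roi"))
  if (!all(dim(map$values) == dim(roi$ecs_mask)))
    stop("map and ROI grids differ")
  one <- function(zmask, label) {
    v <- map$values[zmask]
    ok <- !is.na(v)
    data.frame(zone = label,
               mean = if (any(ok)) mean(v[ok]) else NA_real_,
               n_valid = sum(ok), n_total = sum(zmask),
               frac_invalid = if (sum(zmask) > 0) 1 - sum(ok) / sum(zmask) else NA_real_,
               flagged = !any(ok))
  }
  rbind(one(roi$ecs_mask, "ECS"), one(roi$sf_mask, "sf"), one(roi$dp_mask, "dp"))
}
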