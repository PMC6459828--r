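# full-precision number formatting for text round-trips
.fmt <- function(x) sprintf("%.17g", x)

#' Write an image series as a text array plus JSON sidecar
#'
#' The stack is stored as `<stem>.tsv` (time points stacked row-blocks,
#' 17 significant digits) with acquisition metadata in `<stem>.json`; the
#' ground-truth zone labels, if present, go to `<stem>_labels.tsv`. The
#' round-trip through [read_series()] is lossless.
#'
#' @param series an image series (see [render_series()]).
#' @param stem output path without extension.
#' @return `stem`, invisibly.
#' @export
write_series <- function(series, stem) {
  d <- dim(series$data)
  side <- list(kind = series$protocol$kind,
               time_points = series$protocol$time_points,
               repetition_time = series$protocol$repetition_time,
               fov_mm = series$protocol$fov_mm,
               grid = series$protocol$grid,
               pixel_spacing = series$pixel_spacing,
               displacement = series$displacement,
               sample_id = series$sample_id)
  jsonlite::write_json(side, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA)
  flat <- matrix(aperm(series$data, c(1, 3, 2)), nrow = d[1] * d[3], ncol = d[2])
  writeLines(apply(flat, 1, function(r) paste(.fmt(r), collapse = "\t")),
             paste0(stem, ".tsv"))
  if (!is.null(series$zone))
    utils::write.table(series$zone, paste0(stem, "_labels.tsv"),
                       sep = "\t", row.names = FALSE, col.names = FALSE)
  invisible(stem)
}

#' Read an image series written by [write_series()]
#'
#' @param stem path without extension.
#' @return an image-series list with `data`, `protocol`, `displacement`,
#'   `sample_id`, `pixel_spacing` and (if stored) `zone` and `mask`.
#' @export
read_series <- function(stem) {
  jf <- paste0(stem, ".json")
  if (!file.exists(jf)) stop("sidecar not found: ", jf)
  side <- jsonlite::read_json(jf, simplifyVector = TRUE)
  for (f in c("kind", "time_points", "grid", "pixel_spacing", "displacement"))
    if (is.null(side[[f]])) stop("sidecar missing required field '", f, "'")
  protocol <- qmri_protocol(side$kind, side$time_points, side$repetition_time,
                            side$fov_mm, side$grid)
  rows <- as.integer(side$grid[1]); cols <- as.integer(side$grid[2])
  flat <- as.matrix(utils::read.table(paste0(stem, ".tsv"), sep = "\t"))
  ntp <- nrow(flat) / rows
  if (ntp != length(side$time_points))
    stop("data has ", ntp, " frames but sidecar lists ",
         length(side$time_points), " time points")
  data <- aperm(array(flat, dim = c(rows, ntp, cols)), c(1, 3, 2))
  out <- list(data = data, protocol = protocol,
              displacement = side$displacement, sample_id = side$sample_id,
              pixel_spacing = side$pixel_spacing)
  lf <- paste0(stem, "_labels.tsv")
  if (file.exists(lf)) {
    zone <- as.matrix(utils::read.table(lf, sep = "\t"))
    dimnames(zone) <- NULL
    out$zone <- zone
    out$mask <- zone > 0
  }
  out
}

#' Write / read a tidy cohort table
#'
#' Plain CSV with full-precision numerics; [read_cohort_table()] restores the
#' data.frame.
#' @param table data.frame.
#' @param path CSV path.
#' @export
write_cohort_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_table
#' @export
read_cohort_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Rounded display variant of a numeric table
#'
#' One-decimal rounding of all numeric columns, the printing convention of
#' the summary tables; the full-precision table remains the data of record.
#' @param table data.frame.
#' @param digits decimal places.
#' @export
round_display <- function(table, digits = 1) {
  num <- vapply(table, is.numeric, logical(1))
  table[num] <- lapply(table[num], round, digits = digits)
  table
}

# blue -> cyan -> yellow -> red colour ramp on [0, 1]
.ramp_rgb <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  r <- pmin(pmax(3 * u - 1.5, 0), 1)
  g <- pmin(pmax(1.5 - abs(3 * u - 1.5), 0), 1)
  b <- pmin(pmax(1.5 - 3 * u, 0), 1)
  cbind(r, g, b)
}

#' Render a colour-coded parameter-map overlay
#'
#' Writes an ASCII portable pixmap (PPM, P3): the background image in
#' grayscale with valid map pixels colour-coded on a fixed scale
#' (0-2000 ms for T1 by default). Deterministic: identical inputs produce
#' identical files. An all-invalid map yields the background only, with a
#' warning.
#'
#' @param map a `parameter_map`.
#' @param background numeric matrix of the same shape (e.g. the first
#'   morphological image of the series).
#' @param path output file path (`.ppm`).
#' @param scale colour-scale limits in ms; default 0-2000 for T1, otherwise
#'   0 to the 98th percentile of the valid values.
#' @export
render_overlay <- function(map, background, path, scale = NULL) {
  stopifnot(inherits(map, "parameter_map"))
  if (!all(dim(background) == dim(map$values))) stop("shape mismatch")
  if (is.null(scale)) {
    scale <- if (map$kind == "T1") c(0, 2000) else
      c(0, max(stats::quantile(map$values, 0.98, na.rm = TRUE), 1, na.rm = TRUE))
  }
  bgmax <- max(background, 1e-12)
  gray <- round(255 * pmin(pmax(background / bgmax, 0), 1))
  rgb <- cbind(as.vector(gray), as.vector(gray), as.vector(gray))
  ok <- which(!is.na(map$values))
  if (length(ok) == 0) {
    warning("all map pixels invalid; writing background only")
  } else {
    u <- (map$values[ok] - scale[1]) / (scale[2] - scale[1])
    rgb[ok, ] <- round(255 * .ramp_rgb(u))
  }
  nr <- nrow(background); nc <- ncol(background)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P3", paste(nc, nr),
               paste("# scale_ms", scale[1], scale[2], map$kind), "255"), con)
  # PPM is row-major top-to-bottom
  ord <- as.vector(t(matrix(seq_len(nr * nc), nr, nc)))
  writeLines(apply(rgb[ord, , drop = FALSE], 1, paste, collapse = " "), con)
  invisible(path)
}
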