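#' Mankin sum score from subscores
#'
#' Sum of the four histological subscores: structure (0-6), cellularity
#' (0-3), proteoglycan staining (0-4), tidemark integrity (0-1); range 0-14.
#' Out-of-range components raise an error.
#'
#' @param structure,cellularity,proteoglycan,tidemark integer subscores.
#' @return integer sum score.
#' @export
mankin_sum <- function(structure, cellularity, proteoglycan, tidemark) {
  comp <- c(structure = structure, cellularity = cellularity,
            proteoglycan = proteoglycan, tidemark = tidemark)
  caps <- c(structure = 6, cellularity = 3, proteoglycan = 4, tidemark = 1)
  if (any(comp != round(comp)) || any(comp < 0) || any(comp > caps))
    stop("Mankin subscore out of range: ",
         paste(names(comp)[comp < 0 | comp > caps], collapse = ", "))
  as.integer(sum(comp))
}

#' Dichotomize a Mankin sum score
#'
#' Sum scores 0-4 are intact (`"int"`), 5-8 early degenerative (`"deg"`).
#' Scores above 8 correspond to tissue outside the study population
#' (macroscopically advanced degeneration was excluded) and are labelled
#' `"out-of-study"` rather than guessed into a group.
#'
#' @param mss integer in 0-14 (vectorised).
#' @export
dichotomize <- function(mss) {
  if (any(mss < 0 | mss > 14 | mss != round(mss)))
    stop("MSS must be an integer in 0..14")
  ifelse(mss <= 4, "int", ifelse(mss <= 8, "deg", "out-of-study"))
}

#' Reference interval from the intact group
#'
#' Mean +/- one standard deviation of the intact samples, on the linear
#' scale (`[m - s, m + s]`) or the log scale (`[exp(m - s), exp(m + s)]`
#' with m, s computed on log-values). Values inside the interval read as
#' intact.
#'
#' @param values_int intact-group values, n >= 2 (positive if `scale="log"`).
#' @param scale `"log"` (default, consistent with the global log-transform
#'   policy) or `"linear"`.
#' @param parameter optional identifier carried in the result.
#' @return object of class `reference_interval`: list with `lower`, `upper`,
#'   `scale`, `parameter`, `n`.
#' @export
interval_from_int <- function(values_int, scale = c("log", "linear"),
                              parameter = NA_character_) {
  scale <- match.arg(scale)
  values_int <- values_int[!is.na(values_int)]
  if (length(values_int) < 2) stop("need >= 2 intact values")
  if (scale == "log") {
    if (any(values_int <= 0)) stop("log-scale interval requires positive values")
    m <- mean(log(values_int)); s <- stats::sd(log(values_int))
    lo <- exp(m - s); hi <- exp(m + s)
  } else {
    m <- mean(values_int); s <- stats::sd(values_int)
    lo <- m - s; hi <- m + s
  }
  structure(list(lower = lo, upper = hi, scale = scale,
                 parameter = parameter, n = length(values_int)),
            class = "reference_interval")
}

#' Classify a value against a reference interval
#'
#' Positive (reads intact) iff `lower <= value <= upper`, boundaries
#' inclusive; values outside read degenerative (negative). Missing values
#' are unclassifiable (`NA`). Boundary comparisons carry a 1e-12 relative
#' tolerance so that inclusive bounds survive log/exp round-trips.
#'
#' @param value numeric (vectorised).
#' @param interval a `reference_interval`.
#' @return character vector `"positive"` / `"negative"` with `NA` for
#'   unclassifiable input.
#' @export
classify <- function(value, interval) {
  stopifnot(inherits(interval, "reference_interval"))
  lo <- interval$lower - 1e-12 * abs(interval$lower)
  hi <- interval$upper + 1e-12 * abs(interval$upper)
  ifelse(is.na(value), NA_character_,
         ifelse(value >= lo & value <= hi, "positive", "negative"))
}

#' Sensitivity and specificity for intactness
#'
#' Truth is histological group membership: intact samples are the condition
#' the test detects. Sensitivity is the fraction of intact samples reading
#' positive, specificity the fraction of degenerative samples reading
#' negative. Unclassifiable predictions (`NA`) are excluded from the 2x2
#' table and counted separately.
#'
#' @param predictions `"positive"` / `"negative"` labels (NA allowed).
#' @param truth `"int"` / `"deg"` labels of equal length.
#' @return list with `sensitivity`, `specificity`, counts `tp`, `fn`, `tn`,
#'   `fp`, and `n_excluded`.
#' @export
sens_spec <- function(predictions, truth) {
  if (length(predictions) != length(truth)) stop("length mismatch")
  keep <- !is.na(predictions)
  p <- predictions[keep]; tr <- truth[keep]
  tp <- sum(p == "positive" & tr == "int")
  fn <- sum(p == "negative" & tr == "int")
  tn <- sum(p == "negative" & tr == "deg")
  fp <- sum(p == "positive" & tr == "deg")
  list(sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       tp = tp, fn = fn, tn = tn, fp = fp,
       n_excluded = sum(!keep))
}

#' Combine diagnostic tests
#'
#' Believe-the-positive: the panel is positive if any component test is
#' positive (maximizes sensitivity for intactness). Believe-the-negative:
#' the panel is negative if any component is negative, i.e. positive only
#' when all components are positive (maximizes specificity). Accepts two or
#' more label vectors; the pairwise rule folds associatively.
#'
#' @param ... two or more label vectors (`"positive"`/`"negative"`, equal
#'   lengths; `NA` propagates).
#' @param rule `"believe_positive"` or `"believe_negative"`.
#' @return combined label vector.
#' @export
combine_tests <- function(..., rule = c("believe_positive", "believe_negative")) {
  rule <- match.arg(rule)
  tests <- list(...)
  if (length(tests) == 1 && is.list(tests[[1]]) && !is.character(tests[[1]]))
    tests <- tests[[1]]
  if (length(tests) < 2) stop("need at least two component tests")
  n <- unique(lengths(tests))
  if (length(n) != 1) stop("length mismatch between component tests")
  m <- do.call(cbind, lapply(tests, function(t) t == "positive"))
  any_na <- apply(m, 1, function(r) any(is.na(r)))
  pos <- if (rule == "believe_positive") apply(m, 1, any) else apply(m, 1, all)
  out <- ifelse(pos, "positive", "negative")
  out[any_na] <- NA_character_
  out
}

#' Diagnostic report over a cohort table
#'
#' Builds reference intervals from the intact group for every requested
#' marker (an unloaded parameter value or a relative-change variant),
#' classifies every sample, and tabulates sensitivity and specificity for
#' each single marker and each requested combination.
#'
#' @param wide per-sample wide table from [loading_response_table()].
#' @param zone ROI used for the markers (default `"ECS"`).
#' @param scale interval scale, see [interval_from_int()].
#' @param combinations list of `list(tests = c(...), rule = ...)` entries;
#'   test names are `parameter` for unloaded values or
#'   `parameter:delta2.5` / `parameter:delta5.0` for relative changes.
#' @return list with `intervals` (data.frame), `performance` (data.frame:
#'   test, rule, tp/fn/tn/fp, sensitivity, specificity, n_excluded) and the
#'   per-sample `labels` matrix.
#' @export
diagnostic_report <- function(wide, zone = "ECS", scale = "log",
                              combinations = list()) {
  sub <- wide[wide$zone == zone, ]
  samples <- unique(sub[, c("sample_id", "group")])
  markers <- list()
  for (par in unique(sub$parameter)) {
    s <- sub[sub$parameter == par, ]
    s <- s[match(samples$sample_id, s$sample_id), ]
    markers[[par]] <- list(values = s$d0, scale = scale)
    markers[[paste0(par, ":delta2.5")]] <- list(values = s$`delta2.5`, scale = "linear")
    markers[[paste0(par, ":delta5.0")]] <- list(values = s$`delta5.0`, scale = "linear")
  }
  labels <- intervals <- perf <- list()
  for (nm in names(markers)) {
    v <- markers[[nm]]$values
    sc <- markers[[nm]]$scale   # deltas can be negative: linear scale
    iv <- interval_from_int(v[samples$group == "int"], scale = sc, parameter = nm)
    lab <- classify(v, iv)
    labels[[nm]] <- lab
    ss <- sens_spec(lab, samples$group)
    intervals[[nm]] <- data.frame(test = nm, lower = iv$lower,
                                  upper = iv$upper, scale = sc)
    perf[[nm]] <- data.frame(test = nm, rule = "single",
                             tp = ss$tp, fn = ss$fn, tn = ss$tn, fp = ss$fp,
                             sensitivity = ss$sensitivity,
                             specificity = ss$specificity,
                             n_excluded = ss$n_excluded)
  }
  for (cb in combinations) {
    nm <- paste(paste(cb$tests, collapse = "+"), cb$rule, sep = "|")
    lab <- combine_tests(labels[cb$tests], rule = cb$rule)
    ss <- sens_spec(lab, samples$group)
    perf[[nm]] <- data.frame(test = nm, rule = cb$rule,
                             tp = ss$tp, fn = ss$fn, tn = ss$tn, fp = ss$fp,
                             sensitivity = ss$sensitivity,
                             specificity = ss$specificity,
                             n_excluded = ss$n_excluded)
  }
  list(intervals = do.call(rbind, c(intervals, list(make.row.names = FALSE))),
       performance = do.call(rbind, c(perf, list(make.row.names = FALSE))),
       labels = do.call(cbind, labels),
       samples = samples)
}
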