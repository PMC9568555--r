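# Domain types, unit conventions, CSV interchange, packaged reference constants.
#
# All analysis in this package happens on dB magnitudes:
#   displacement: dB re 1 um/Pa,  velocity: dB re 1 um/s/Pa.

#' Canonical audiological frequency grid
#'
#' The eight frequencies commonly used to report hearing-related measurements,
#' onto which all METF curves are interpolated: 125, 250, 500, 1000, 2000,
#' 3000, 4000 and 6000 Hz.
#'
#' @return Numeric vector of 8 frequencies in Hz, strictly increasing.
#' @export
#' @examples
#' audiological_grid()
audiological_grid <- function() {
  c(125, 250, 500, 1000, 2000, 3000, 4000, 6000)
}

#' Validate a frequency grid
#'
#' @param frequencies_hz Numeric vector; must be finite, positive and strictly
#'   increasing.
#' @return The validated grid, invisibly usable as input elsewhere.
#' @export
validate_grid <- function(frequencies_hz) {
  if (!is.numeric(frequencies_hz) || length(frequencies_hz) == 0) {
    stop("frequency grid must be a nonempty numeric vector", call. = FALSE)
  }
  if (any(!is.finite(frequencies_hz)) || any(frequencies_hz <= 0)) {
    stop("grid frequencies must be finite and > 0", call. = FALSE)
  }
  if (is.unsorted(frequencies_hz, strictly = TRUE)) {
    stop("grid frequencies must be strictly increasing", call. = FALSE)
  }
  frequencies_hz
}

metf_units <- c("displacement", "velocity")

#' dB label for a unit
#' @param unit `"displacement"` or `"velocity"`.
#' @return Human-readable dB reference label.
#' @export
unit_label <- function(unit) {
  unit <- match.arg(unit, metf_units)
  switch(unit,
    displacement = "dB re 1 um/Pa",
    velocity     = "dB re 1 um/s/Pa"
  )
}

# columns of the long-format interchange table, in frozen order
metf_columns <- c(
  "tb_id", "group", "method", "frequency_hz", "metf_db",
  "unit", "angle_deg", "angle_corrected"
)

#' Construct a single METF curve
#'
#' One temporal bone's magnitude-versus-frequency record together with its
#' provenance (research group, measurement method, laser incidence angle).
#' This is the unit of validation against a reference range.
#'
#' @param tb_id Specimen identifier (nonempty string).
#' @param frequency_hz Frequencies in Hz (strictly increasing, positive).
#' @param metf_db Finite dB magnitudes, same length as `frequency_hz`.
#' @param group Research group label (e.g. `"Dresden"`, `"synthetic"`).
#' @param method Measurement method label, one of `"A"`, `"B"`, `"C"`, `"D"`
#'   (A = single-point LDV on the stapes footplate).
#' @param unit `"displacement"` or `"velocity"`.
#' @param angle_deg Optional laser incidence angle in degrees, in `[0, 90)`.
#' @param angle_corrected Logical; has the cos-angle correction been applied?
#' @return Object of class `metf_curve`.
#' @export
metf_curve <- function(tb_id, frequency_hz, metf_db, group = "synthetic",
                       method = "A", unit = "displacement", angle_deg = NA_real_,
                       angle_corrected = FALSE) {
  stopifnot(is.character(tb_id), length(tb_id) == 1, nzchar(tb_id))
  unit <- match.arg(unit, metf_units)
  validate_grid(frequency_hz)
  if (length(metf_db) != length(frequency_hz)) {
    stop("metf_db and frequency_hz must have equal length", call. = FALSE)
  }
  if (any(!is.finite(metf_db))) {
    stop("magnitudes must be finite dB values", call. = FALSE)
  }
  if (!is.na(angle_deg) && (angle_deg < 0 || angle_deg >= 90)) {
    stop("angle_deg must lie in [0, 90)", call. = FALSE)
  }
  structure(
    list(
      tb_id = tb_id, group = as.character(group), method = as.character(method),
      unit = unit, angle_deg = as.numeric(angle_deg),
      angle_corrected = isTRUE(angle_corrected),
      frequency_hz = as.numeric(frequency_hz), metf_db = as.numeric(metf_db)
    ),
    class = "metf_curve"
  )
}

#' @export
print.metf_curve <- function(x, ...) {
  cat(sprintf(
    "<metf_curve> %s [%s/%s] %s, %d points (%g-%g Hz)%s\n",
    x$tb_id, x$group, x$method, unit_label(x$unit), length(x$frequency_hz),
    min(x$frequency_hz), max(x$frequency_hz),
    if (isTRUE(x$angle_corrected)) ", angle-corrected" else ""
  ))
  invisible(x)
}

#' Construct/validate a long-format METF table
#'
#' The unit of statistical analysis: one row per (specimen, frequency) data
#' point with columns `tb_id, group, method, frequency_hz, metf_db, unit,
#' angle_deg, angle_corrected`. `(tb_id, frequency_hz)` must be unique within
#' a unit and magnitudes finite.
#'
#' @param df A data.frame carrying at least the columns above (`angle_deg`,
#'   `angle_corrected` filled with defaults if absent).
#' @return The validated table with class `metf_table`, rows ordered by
#'   `(tb_id, frequency_hz)`.
#' @export
metf_table <- function(df) {
  stopifnot(is.data.frame(df))
  if (is.null(df$angle_deg)) df$angle_deg <- NA_real_
  if (is.null(df$angle_corrected)) df$angle_corrected <- FALSE
  missing_cols <- setdiff(metf_columns, names(df))
  if (length(missing_cols) > 0) {
    stop(sprintf("missing required column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  df <- df[, metf_columns, drop = FALSE]
  df$tb_id <- as.character(df$tb_id)
  df$group <- as.character(df$group)
  df$method <- as.character(df$method)
  df$unit <- as.character(df$unit)
  df$frequency_hz <- as.numeric(df$frequency_hz)
  df$metf_db <- as.numeric(df$metf_db)
  df$angle_deg <- as.numeric(df$angle_deg)
  df$angle_corrected <- as.logical(df$angle_corrected)
  if (nrow(df) > 0) {
    if (!all(df$unit %in% metf_units)) {
      stop("unit must be 'displacement' or 'velocity'", call. = FALSE)
    }
    if (any(!is.finite(df$metf_db))) {
      stop("magnitudes must be finite dB values", call. = FALSE)
    }
    if (any(!is.finite(df$frequency_hz)) || any(df$frequency_hz <= 0)) {
      stop("frequencies must be finite and > 0", call. = FALSE)
    }
    key <- paste(df$unit, df$tb_id, df$frequency_hz)
    if (anyDuplicated(key)) {
      dup <- df[duplicated(key), , drop = FALSE]
      stop(sprintf("duplicate (tb_id, frequency) pair(s), e.g. %s @ %g Hz",
                   dup$tb_id[1], dup$frequency_hz[1]), call. = FALSE)
    }
    df <- df[order(df$tb_id, df$frequency_hz), , drop = FALSE]
    rownames(df) <- NULL
  }
  class(df) <- c("metf_table", "data.frame")
  df
}

#' Split a METF table into curves
#'
#' @param table A `metf_table`.
#' @return Named list of `metf_curve` objects, one per `tb_id`.
#' @export
table_to_curves <- function(table) {
  table <- metf_table(table)
  out <- lapply(split(as.data.frame(table), table$tb_id), function(d) {
    d <- d[order(d$frequency_hz), ]
    metf_curve(d$tb_id[1], d$frequency_hz, d$metf_db,
               group = d$group[1], method = d$method[1], unit = d$unit[1],
               angle_deg = d$angle_deg[1], angle_corrected = d$angle_corrected[1])
  })
  out[order(names(out))]
}

#' Read a long-format METF CSV
#'
#' Expects the frozen schema
#' `tb_id,group,method,frequency_hz,metf_db,unit,angle_deg,angle_corrected`.
#' Rows whose numeric fields cannot be parsed are rejected with a
#' row-addressed error.
#'
#' @param path Path to an existing CSV file.
#' @return A `metf_table`.
#' @export
read_metf_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  missing_cols <- setdiff(metf_columns, names(raw))
  if (length(missing_cols) > 0) {
    stop(sprintf("schema error in %s: missing column(s) %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  parse_num <- function(x) suppressWarnings(as.numeric(x))
  num_ok <- function(orig, parsed) is.na(parsed) & !(is.na(orig) | orig %in% c("", "NA"))
  freq <- parse_num(raw$frequency_hz)
  mag <- parse_num(raw$metf_db)
  ang <- parse_num(raw$angle_deg)
  bad <- which(num_ok(raw$frequency_hz, freq) | num_ok(raw$metf_db, mag) |
                 num_ok(raw$angle_deg, ang))
  if (length(bad) > 0) {
    stop(sprintf("unparseable numeric value(s) in %s at data row(s): %s", path,
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  metf_table(data.frame(
    tb_id = raw$tb_id, group = raw$group, method = raw$method,
    frequency_hz = freq, metf_db = mag, unit = raw$unit,
    angle_deg = ang,
    angle_corrected = as.logical(raw$angle_corrected),
    stringsAsFactors = FALSE
  ))
}

#' Write a long-format METF CSV
#'
#' Writes the frozen column order at full float precision (17 significant
#' digits) so files round-trip exactly and are diffable across runs.
#'
#' @param table A valid `metf_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metf_csv <- function(table, path) {
  table <- metf_table(table)  # re-validates; non-finite magnitudes rejected here
  out <- as.data.frame(table)
  for (col in c("frequency_hz", "metf_db", "angle_deg")) {
    out[[col]] <- ifelse(is.na(out[[col]]), "NA", sprintf("%.17g", out[[col]]))
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- reference tables -------------------------------------------------------

reference_columns <- c(
  "unit", "frequency_hz", "n", "mean_db", "ci95_lo", "ci95_hi",
  "ti90_lo", "ti90_hi", "ti95_lo", "ti95_hi", "ti99_lo", "ti99_hi"
)

#' Construct/validate a reference table
#'
#' Per-frequency mean, 95% confidence interval of the mean, and two-sided
#' tolerance interval bounds for a stated unit. Enforces the ordering
#' `ti_lo < ci_lo <= mean <= ci_hi < ti_hi` and tolerance-interval widths
#' non-decreasing in the population proportion p.
#'
#' @param df Data frame with columns
#'   `unit, frequency_hz, n, mean_db, ci95_lo, ci95_hi, ti90_lo, ti90_hi,
#'   ti95_lo, ti95_hi, ti99_lo, ti99_hi` (TI columns may be `NA` where a
#'   proportion was not computed).
#' @param alpha Confidence parameter of the tolerance intervals (default 0.05,
#'   i.e. 95% confidence).
#' @param n_curves,n_points Optional provenance metadata: number of curves and
#'   data points the table was built from.
#' @return A `reference_table` (data.frame subclass) with `alpha`, `n_curves`
#'   and `n_points` attributes.
#' @export
reference_table <- function(df, alpha = 0.05, n_curves = NA_integer_,
                            n_points = NA_integer_) {
  stopifnot(is.data.frame(df))
  missing_cols <- setdiff(reference_columns, names(df))
  if (length(missing_cols) > 0) {
    stop(sprintf("missing reference column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  df <- df[, reference_columns, drop = FALSE]
  df$unit <- as.character(df$unit)
  if (!all(df$unit %in% metf_units)) {
    stop("unit must be 'displacement' or 'velocity'", call. = FALSE)
  }
  for (col in reference_columns[-1]) df[[col]] <- as.numeric(df[[col]])
  ok <- df$ci95_lo <= df$mean_db & df$mean_db <= df$ci95_hi
  if (any(!ok)) stop("CI of the mean must contain the mean", call. = FALSE)
  for (p in c("90", "95", "99")) {
    lo <- df[[paste0("ti", p, "_lo")]]
    hi <- df[[paste0("ti", p, "_hi")]]
    have <- !is.na(lo) & !is.na(hi)
    if (any(have & (lo >= df$ci95_lo | hi <= df$ci95_hi))) {
      stop(sprintf("TI%s must strictly contain the CI of the mean", p),
           call. = FALSE)
    }
  }
  w90 <- df$ti90_hi - df$ti90_lo
  w95 <- df$ti95_hi - df$ti95_lo
  w99 <- df$ti99_hi - df$ti99_lo
  cmp <- function(a, b) any(!is.na(a) & !is.na(b) & a > b + 1e-12)
  if (cmp(w90, w95) || cmp(w95, w99)) {
    stop("TI widths must be non-decreasing in p", call. = FALSE)
  }
  df <- df[order(df$unit, df$frequency_hz), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("reference_table", "data.frame"),
            alpha = alpha, n_curves = n_curves, n_points = n_points)
}

#' Write a reference table CSV
#' @param reference A `reference_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reference_csv <- function(reference, path) {
  stopifnot(inherits(reference, "reference_table"))
  out <- as.data.frame(reference)
  num <- setdiff(reference_columns, "unit")
  for (col in num) {
    out[[col]] <- ifelse(is.na(out[[col]]), "NA", sprintf("%.17g", out[[col]]))
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a reference table CSV
#' @param path CSV written by [write_reference_csv()].
#' @param alpha Confidence parameter to record (default 0.05).
#' @return A `reference_table`.
#' @export
read_reference_csv <- function(path, alpha = 0.05) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  reference_table(raw, alpha = alpha)
}

# Published multicenter reference values: per-frequency mean, 95% CI of the
# mean and two-sided (0.95, 0.95) tolerance interval, for stapes footplate
# displacement (dB re 1 um/Pa) and velocity (dB re 1 um/s/Pa). Built from 366
# single-point-LDV (method A) METF curves / 2321 data points after Tukey
# screening. 90%/99% TI columns were published only in a supplementary
# spreadsheet and are not carried here (NA); consumers fall back to the 95% TI.
.packaged_reference_values <- local({
  disp <- data.frame(
    frequency_hz = c(125, 250, 500, 1000, 2000, 3000, 4000, 6000),
    mean_db = c(-31.6, -34.2, -33.2, -34.4, -45.7, -53.2, -57.8, -67.0),
    ci95_lo = c(-32.2, -34.8, -33.8, -34.9, -46.3, -54.0, -58.7, -68.0),
    ci95_hi = c(-30.9, -33.6, -32.5, -33.8, -45.0, -52.5, -56.9, -66.1),
    ti95_lo = c(-43.2, -46.1, -45.8, -44.7, -58.0, -68.1, -76.0, -85.5),
    ti95_hi = c(-19.9, -22.3, -20.5, -24.0, -33.3, -38.4, -39.6, -48.7)
  )
  vel <- data.frame(
    frequency_hz = c(125, 250, 500, 1000, 2000, 3000, 4000, 6000),
    mean_db = c(26.3, 29.7, 36.8, 41.6, 36.3, 32.3, 30.2, 24.4),
    ci95_lo = c(25.6, 29.1, 36.1, 41.1, 35.7, 31.5, 29.3, 23.5),
    ci95_hi = c(27.0, 30.3, 37.4, 42.1, 36.9, 33.0, 31.1, 25.4),
    ti95_lo = c(14.7, 17.8, 24.1, 31.3, 24.0, 17.4, 12.0, 6.0),
    ti95_hi = c(38.0, 41.6, 49.4, 52.0, 48.7, 47.1, 48.4, 42.9)
  )
  list(displacement = disp, velocity = vel)
})

#' Packaged METF reference table
#'
#' The published multicenter reference constants: per-frequency mean, 95% CI
#' of the mean and the two-sided 95% tolerance interval on the audiological
#' grid, for stapes footplate displacement or velocity. Metadata records 366
#' curves / 2321 points (the source also quotes 362 measurements in one place;
#' the discrepancy is documented, 366 is what the reference-figure caption
#' states). Per-frequency `n` was not published and is `NA`. The 90%/99% TI
#' columns live only in a supplementary spreadsheet and are `NA`; consumers
#' such as [validate_curve()] fall back to the 95% TI.
#'
#' @param unit `"displacement"` (dB re 1 um/Pa) or `"velocity"`
#'   (dB re 1 um/s/Pa).
#' @return A `reference_table`.
#' @export
#' @examples
#' packaged_reference("displacement")
packaged_reference <- function(unit = c("displacement", "velocity")) {
  unit <- match.arg(unit)
  v <- .packaged_reference_values[[unit]]
  df <- data.frame(
    unit = unit, frequency_hz = v$frequency_hz, n = NA_real_,
    mean_db = v$mean_db, ci95_lo = v$ci95_lo, ci95_hi = v$ci95_hi,
    ti90_lo = NA_real_, ti90_hi = NA_real_,
    ti95_lo = v$ti95_lo, ti95_hi = v$ti95_hi,
    ti99_lo = NA_real_, ti99_hi = NA_real_,
    stringsAsFactors = FALSE
  )
  reference_table(df, alpha = 0.05, n_curves = 366L, n_points = 2321L)
}

# ---- unit conversion and angle correction -----------------------------------

#' dB offset between displacement and velocity magnitudes
#'
#' For a sinusoid at frequency f, velocity magnitude = displacement magnitude
#' times 2*pi*f, i.e. +20*log10(2*pi*f) dB.
#'
#' @param frequency_hz Frequencies in Hz (> 0).
#' @return Offset in dB to add to displacement dB to obtain velocity dB.
#' @export
velocity_offset_db <- function(frequency_hz) {
  if (any(frequency_hz <= 0)) stop("frequency must be > 0", call. = FALSE)
  20 * log10(2 * pi * frequency_hz)
}

#' Convert a curve or table between displacement and velocity
#'
#' Applies the exact per-frequency affine conversion
#' `velocity_db = displacement_db + 20*log10(2*pi*f)` (and its inverse).
#' Metadata is preserved; the conversion is a bijection at fixed frequency.
#'
#' @param x A `metf_curve` or `metf_table`.
#' @param target_unit `"displacement"` or `"velocity"`; must differ from the
#'   current unit.
#' @return Object of the same class in the target unit.
#' @export
convert_unit <- function(x, target_unit) UseMethod("convert_unit")

#' @export
convert_unit.metf_curve <- function(x, target_unit) {
  target_unit <- match.arg(target_unit, metf_units)
  if (identical(x$unit, target_unit)) {
    stop("curve is already in the target unit", call. = FALSE)
  }
  offset <- velocity_offset_db(x$frequency_hz)
  x$metf_db <- if (target_unit == "velocity") x$metf_db + offset else x$metf_db - offset
  x$unit <- target_unit
  x
}

#' @export
convert_unit.metf_table <- function(x, target_unit) {
  target_unit <- match.arg(target_unit, metf_units)
  if (any(x$unit == target_unit)) {
    stop("table already contains rows in the target unit", call. = FALSE)
  }
  offset <- velocity_offset_db(x$frequency_hz)
  x$metf_db <- if (target_unit == "velocity") x$metf_db + offset else x$metf_db - offset
  x$unit <- target_unit
  metf_table(x)
}

#' Angle-correction magnitude in dB
#'
#' A laser beam hitting the stapes footplate at incidence angle theta from its
#' normal measures `d_actual * cos(theta)`, underestimating the true motion;
#' the correction adds `-20*log10(cos(theta))` dB.
#'
#' @param theta_deg Angle(s) in degrees, in `[0, 90)`.
#' @return Correction in dB (>= 0, strictly increasing in theta).
#' @export
#' @examples
#' angle_correction_db(42)  # ~2.6 dB
angle_correction_db <- function(theta_deg) {
  if (any(theta_deg < 0 | theta_deg >= 90)) {
    stop("theta must lie in [0, 90) degrees", call. = FALSE)
  }
  -20 * log10(cos(theta_deg * pi / 180))
}

#' Apply the cos-angle correction to a curve
#'
#' Adds `-20*log10(cos(theta))` dB to every magnitude and marks the curve as
#' corrected. Refuses to correct twice.
#'
#' @param curve A `metf_curve` with `angle_corrected = FALSE`.
#' @param theta_deg Incidence angle in degrees, `[0, 90)`. Defaults to the
#'   curve's recorded `angle_deg`.
#' @return The corrected `metf_curve` (with `angle_deg` recorded).
#' @export
apply_angle_correction <- function(curve, theta_deg = curve$angle_deg) {
  stopifnot(inherits(curve, "metf_curve"))
  if (isTRUE(curve$angle_corrected)) {
    stop("curve is already angle-corrected", call. = FALSE)
  }
  if (is.na(theta_deg)) stop("no angle available for correction", call. = FALSE)
  curve$metf_db <- curve$metf_db + angle_correction_db(theta_deg)
  curve$angle_deg <- as.numeric(theta_deg)
  curve$angle_corrected <- TRUE
  curve
}

# ---- configuration and logging ----------------------------------------------

#' Pipeline configuration
#'
#' Bundle of the tunable parameters shared by the screening and reference
#' stages, with the conventional defaults: Tukey multiplier k = 1.75, core
#' band 500-4000 Hz, alpha = 0.05, tolerance proportions (0.90, 0.95, 0.99).
#'
#' @param outlier_k Tukey fence multiplier (> 0).
#' @param core_band_hz Length-2 band in Hz inside which an outlier discards the
#'   whole curve.
#' @param alpha Type-I error level in (0, 1).
#' @param ti_proportions Population proportions for tolerance intervals, each
#'   in (0, 1).
#' @param quality_profile Laboratory quality-gate profile name
#'   (`"dresden"`, `"hannover"` or `"shanghai"`).
#' @param interp_axis Interpolation axis: `"hz"` (linear in Hz, default) or
#'   `"log"` (linear in log10 f).
#' @param quantile_type Quantile convention for fences (R types 1-9; default 7,
#'   linear interpolation of order statistics).
#' @param seed Integer master seed for any stochastic step.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(outlier_k = 1.75, core_band_hz = c(500, 4000),
                            alpha = 0.05, ti_proportions = c(0.90, 0.95, 0.99),
                            quality_profile = "dresden", interp_axis = "hz",
                            quantile_type = 7, seed = 1L) {
  stopifnot(outlier_k > 0, length(core_band_hz) == 2,
            core_band_hz[1] < core_band_hz[2],
            alpha > 0, alpha < 1,
            all(ti_proportions > 0 & ti_proportions < 1))
  quality_profile <- match.arg(quality_profile, c("dresden", "hannover", "shanghai"))
  interp_axis <- match.arg(interp_axis, c("hz", "log"))
  structure(
    list(outlier_k = outlier_k, core_band_hz = as.numeric(core_band_hz),
         alpha = alpha, ti_proportions = sort(ti_proportions),
         quality_profile = quality_profile, interp_axis = interp_axis,
         quantile_type = as.integer(quantile_type), seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

# verbosity-gated progress messages, to stderr
metfref_log <- function(...) {
  if (isTRUE(getOption("metfref.verbose", FALSE))) {
    message("[metfref] ", sprintf(...))
  }
  invisible(NULL)
}
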