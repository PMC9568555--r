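# From gated transfer estimates to analysis-ready METF tables.
#
# Pipeline order is fixed: quality gating -> whole-curve validity check ->
# interpolation onto the audiological grid -> (downstream) outlier screening.

#' Raw curve with validity mask
#'
#' A magnitude-versus-frequency record on an arbitrary acquisition grid,
#' together with the per-point validity mask produced by [quality_gate()].
#'
#' @param frequency_hz Source frequencies (strictly increasing, > 0).
#' @param magnitude_db dB magnitudes, same length.
#' @param valid Logical mask, recycled if scalar.
#' @return A `raw_curve` list.
#' @export
raw_curve <- function(frequency_hz, magnitude_db, valid = TRUE) {
  validate_grid(frequency_hz)
  stopifnot(length(magnitude_db) == length(frequency_hz))
  valid <- rep_len(as.logical(valid), length(frequency_hz))
  structure(list(frequency_hz = as.numeric(frequency_hz),
                 magnitude_db = as.numeric(magnitude_db), valid = valid),
            class = "raw_curve")
}

#' Raw curve from a gated transfer estimate
#'
#' @param estimate A `transfer_estimate`.
#' @param mask Validity mask (e.g. from [quality_gate()]); default all valid.
#' @return A `raw_curve` on the estimate's frequency support.
#' @export
as_raw_curve <- function(estimate, mask = TRUE) {
  raw_curve(estimate$frequency_hz, estimate$magnitude_db, valid = mask)
}

#' Interpolate a raw curve onto a frequency grid
#'
#' Linear interpolation of dB magnitude between the bracketing *valid* source
#' points; targets with an exact valid source match copy the value unchanged;
#' targets without valid brackets are left missing - never extrapolated.
#' The interpolation axis is linear in Hz by default; `axis = "log"` uses
#' log10-frequency instead (recorded in the result).
#'
#' @param raw A `raw_curve`.
#' @param grid Target frequencies (default the audiological grid).
#' @param axis `"hz"` or `"log"`.
#' @param tb_id,group,method,unit,angle_deg,angle_corrected Metadata forwarded
#'   to the resulting [metf_curve()].
#' @return A `metf_curve` holding only the grid frequencies that could be
#'   interpolated; attribute `interp_axis` records the axis used.
#' @export
interpolate_to_grid <- function(raw, grid = audiological_grid(), axis = c("hz", "log"),
                                tb_id = "TB1", group = "synthetic", method = "A",
                                unit = "displacement", angle_deg = NA_real_,
                                angle_corrected = FALSE) {
  stopifnot(inherits(raw, "raw_curve"))
  axis <- match.arg(axis)
  validate_grid(grid)
  f <- raw$frequency_hz[raw$valid]
  y <- raw$magnitude_db[raw$valid]
  if (length(f) == 0) stop("curve has no valid points", call. = FALSE)
  tx <- if (axis == "log") log10(f) else f
  gx <- if (axis == "log") log10(grid) else grid
  vals <- if (length(f) == 1) {
    ifelse(abs(gx - tx) < 1e-12, y, NA_real_)
  } else {
    stats::approx(tx, y, xout = gx, method = "linear", rule = 1, ties = "ordered")$y
  }
  keep <- !is.na(vals)
  if (!any(keep)) stop("no grid frequency could be interpolated", call. = FALSE)
  out <- metf_curve(tb_id, grid[keep], vals[keep], group = group, method = method,
                    unit = unit, angle_deg = angle_deg,
                    angle_corrected = angle_corrected)
  attr(out, "interp_axis") <- axis
  out
}

#' Whole-curve validity rule for the core band
#'
#' A measurement is usable only if every source point needed to interpolate
#' the grid targets inside the core band (1000-4000 Hz) is valid: for each
#' such target, its exact source match or its two natural bracketing source
#' points. Invalid points affecting only the spectral edges are tolerated
#' here (they are handled later by truncation).
#'
#' @param raw A `raw_curve`.
#' @param grid Target grid (default audiological).
#' @param core_band_hz Inclusive band whose targets must be interpolable from
#'   valid points (default `c(1000, 4000)`).
#' @return `TRUE` (keep) or `FALSE` (reject whole curve).
#' @export
enforce_core_validity <- function(raw, grid = audiological_grid(),
                                  core_band_hz = c(1000, 4000)) {
  stopifnot(inherits(raw, "raw_curve"))
  targets <- grid[grid >= core_band_hz[1] & grid <= core_band_hz[2]]
  f <- raw$frequency_hz
  for (t in targets) {
    exact <- which(abs(f - t) < 1e-9)
    needed <- if (length(exact) > 0) {
      exact[1]
    } else {
      lo <- which(f < t)
      hi <- which(f > t)
      if (length(lo) == 0 || length(hi) == 0) return(FALSE)  # cannot bracket
      c(lo[which.max(f[lo])], hi[which.min(f[hi])])
    }
    if (!all(raw$valid[needed])) return(FALSE)
  }
  TRUE
}

#' Assemble curves into a long-format table
#'
#' @param curves List of `metf_curve` objects sharing one unit.
#' @return A `metf_table` with deterministic row order (tb_id, frequency).
#' @export
assemble_table <- function(curves) {
  if (length(curves) == 0) {
    return(metf_table(data.frame(
      tb_id = character(), group = character(), method = character(),
      frequency_hz = numeric(), metf_db = numeric(), unit = character(),
      angle_deg = numeric(), angle_corrected = logical(),
      stringsAsFactors = FALSE
    )))
  }
  stopifnot(all(vapply(curves, inherits, logical(1), "metf_curve")))
  units <- unique(vapply(curves, function(c) c$unit, character(1)))
  if (length(units) > 1) {
    stop("curves mix units; convert before assembling", call. = FALSE)
  }
  rows <- lapply(curves, function(c) {
    data.frame(tb_id = c$tb_id, group = c$group, method = c$method,
               frequency_hz = c$frequency_hz, metf_db = c$metf_db,
               unit = c$unit, angle_deg = c$angle_deg,
               angle_corrected = c$angle_corrected, stringsAsFactors = FALSE)
  })
  metf_table(do.call(rbind, rows))
}

#' Run gating, validity check and interpolation for a batch of estimates
#'
#' Applies the fixed pipeline order (quality gate, core-band validity,
#' interpolation) to a list of transfer estimates and assembles the survivors
#' into a table. Each step is logged when `options(metfref.verbose = TRUE)`.
#'
#' @param estimates Named list of `transfer_estimate` objects (names become
#'   tb_ids).
#' @param profile Quality-gate profile (see [quality_gate()]).
#' @param grid Target grid.
#' @param axis Interpolation axis.
#' @param ... Metadata forwarded to [interpolate_to_grid()] (`group`,
#'   `method`, `unit`, ...).
#' @return List with `table` (a `metf_table`) and `rejected` (character vector
#'   of tb_ids failing the core-band validity rule).
#' @export
preprocess_estimates <- function(estimates, profile = "dresden",
                                 grid = audiological_grid(), axis = "hz", ...) {
  stopifnot(length(estimates) > 0)
  ids <- names(estimates)
  if (is.null(ids)) ids <- sprintf("TB%03d", seq_along(estimates))
  curves <- list()
  rejected <- character()
  for (i in seq_along(estimates)) {
    est <- estimates[[i]]
    mask <- quality_gate(est, profile)
    metfref_log("quality gate [%s]: %d/%d points valid", ids[i], sum(mask), length(mask))
    raw <- as_raw_curve(est, mask)
    if (!enforce_core_validity(raw, grid)) {
      metfref_log("core-band validity [%s]: rejected", ids[i])
      rejected <- c(rejected, ids[i])
      next
    }
    curves[[ids[i]]] <- interpolate_to_grid(raw, grid, axis = axis, tb_id = ids[i], ...)
    metfref_log("interpolated [%s] onto %d grid points", ids[i],
                length(curves[[ids[i]]]$frequency_hz))
  }
  list(table = assemble_table(unname(curves)), rejected = rejected)
}
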