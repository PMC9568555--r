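# Applying a reference range to new measurements: per-curve verdicts,
# study-mean comparison, impact of a single extreme measurement, and the
# aggregated guideline report.

ti_cols_for <- function(reference, ti_p) {
  tag <- sprintf("%02d", round(100 * ti_p))
  lo <- reference[[paste0("ti", tag, "_lo")]]
  hi <- reference[[paste0("ti", tag, "_hi")]]
  if (is.null(lo) || all(is.na(lo))) return(NULL)
  list(lo = lo, hi = hi)
}

#' Validate one METF curve against a reference range
#'
#' Checks per-frequency containment in the reference tolerance interval.
#' Violations confined to the spectral edges (f < 500 Hz or f > 4000 Hz)
#' yield `valid_after_truncation` (the offending edge bands may be removed);
#' any violation inside 500-4000 Hz yields `flagged` - the curve is never
#' auto-excluded, the decision is the researcher's (undetected pathology,
#' measurement error, or a genuinely unusual but normal ear). A violation at
#' a single isolated frequency is annotated as a possible narrow-band
#' resonance/antiresonance.
#'
#' @param curve A `metf_curve` in the reference's unit (angle-corrected if
#'   the angle is known).
#' @param reference A `reference_table`.
#' @param ti_p Tolerance proportion to check against (default 0.95). Falls
#'   back to 0.95 if the requested proportion's columns are absent from the
#'   reference (e.g. the packaged table), with a note.
#' @param core_band_hz Band within which a violation flags the curve.
#' @return A `validation_verdict` list: `tb_id`, `status` (`valid`,
#'   `valid_after_truncation` or `flagged`), `violations` (data frame
#'   `frequency_hz, direction, exceedance_db`), `truncation_hz` (frequencies
#'   removed by truncation), `truncated_curve`, `ti_p_used`, `notes`.
#' @export
validate_curve <- function(curve, reference, ti_p = 0.95,
                           core_band_hz = c(500, 4000)) {
  stopifnot(inherits(curve, "metf_curve"), inherits(reference, "reference_table"))
  if (!all(reference$unit == curve$unit)) {
    stop("curve and reference units differ; convert first", call. = FALSE)
  }
  notes <- character()
  ti <- ti_cols_for(reference, ti_p)
  ti_used <- ti_p
  if (is.null(ti)) {
    ti <- ti_cols_for(reference, 0.95)
    ti_used <- 0.95
    if (is.null(ti)) stop("reference carries no usable TI columns", call. = FALSE)
    notes <- c(notes, sprintf(
      "requested %g%% TI not available in reference; fell back to 95%% TI",
      100 * ti_p))
  }
  idx <- match(curve$frequency_hz, reference$frequency_hz)
  shared <- which(!is.na(idx))
  if (length(shared) == 0) {
    stop("curve and reference share no frequencies", call. = FALSE)
  }
  f <- curve$frequency_hz[shared]
  v <- curve$metf_db[shared]
  lo <- ti$lo[idx[shared]]
  hi <- ti$hi[idx[shared]]
  below <- v < lo
  above <- v > hi
  viol <- data.frame(
    frequency_hz = f[below | above],
    direction = c(rep("below", sum(below)), rep("above", sum(above)))[
      order(c(which(below), which(above)))],
    exceedance_db = pmax(lo - v, v - hi)[below | above]
  )
  viol <- viol[order(viol$frequency_hz), ]
  rownames(viol) <- NULL
  in_core <- viol$frequency_hz >= core_band_hz[1] &
    viol$frequency_hz <= core_band_hz[2]
  truncation_hz <- numeric()
  truncated_curve <- curve
  if (nrow(viol) == 0) {
    status <- "valid"
  } else if (any(in_core)) {
    status <- "flagged"
    notes <- c(notes, paste(
      "out-of-range inside the 500-4000 Hz core band; curve reported, not",
      "auto-excluded - researcher judgement required"))
  } else {
    status <- "valid_after_truncation"
    low_bad <- viol$frequency_hz[viol$frequency_hz < core_band_hz[1]]
    high_bad <- viol$frequency_hz[viol$frequency_hz > core_band_hz[2]]
    drop <- rep(FALSE, length(curve$frequency_hz))
    if (length(low_bad) > 0) drop <- drop | curve$frequency_hz <= max(low_bad)
    if (length(high_bad) > 0) drop <- drop | curve$frequency_hz >= min(high_bad)
    truncation_hz <- curve$frequency_hz[drop]
    truncated_curve <- metf_curve(curve$tb_id, curve$frequency_hz[!drop],
                                  curve$metf_db[!drop], group = curve$group,
                                  method = curve$method, unit = curve$unit,
                                  angle_deg = curve$angle_deg,
                                  angle_corrected = curve$angle_corrected)
  }
  if (nrow(viol) == 1) {
    notes <- c(notes, paste(
      "single-frequency violation: possibly a narrow-band resonance or",
      "antiresonance (peak/notch) in an otherwise normal METF"))
  }
  structure(
    list(tb_id = curve$tb_id, status = status, violations = viol,
         truncation_hz = truncation_hz, truncated_curve = truncated_curve,
         ti_p_used = ti_used, notes = notes),
    class = "validation_verdict"
  )
}

#' @export
print.validation_verdict <- function(x, ...) {
  cat(sprintf("<validation_verdict> %s: %s (%d violation(s), %g%% TI)\n",
              x$tb_id, x$status, nrow(x$violations), 100 * x$ti_p_used))
  if (nrow(x$violations) > 0) print(x$violations)
  for (n in x$notes) cat("  note:", n, "\n")
  invisible(x)
}

#' Compare a study's mean curve to the reference mean
#'
#' Per-frequency deviation of the study mean from the reference mean, with an
#' advisory flag wherever |deviation| exceeds the threshold (default 6 dB,
#' the plausible upper bound for a between-laboratory offset). Also reports
#' whether the study mean lies inside the reference's 95% CI of the mean -
#' with the caveat that for small studies this is unlikely even for perfectly
#' normal data, because that CI reflects the reference's large n.
#'
#' @param study A nonempty `metf_table` in the reference's unit.
#' @param reference A `reference_table`.
#' @param threshold_db Advisory threshold (default 6).
#' @return Data frame `frequency_hz, n, study_mean_db, reference_mean_db,
#'   deviation_db, advisory, in_reference_ci`; attributes `threshold_db` and
#'   `caveat`.
#' @export
compare_study_mean <- function(study, reference, threshold_db = 6) {
  study <- metf_table(study)
  stopifnot(nrow(study) > 0, inherits(reference, "reference_table"))
  if (!all(reference$unit == study$unit[1]) || length(unique(study$unit)) != 1) {
    stop("study and reference units differ; convert first", call. = FALSE)
  }
  by_f <- split(study$metf_db, study$frequency_hz)
  f <- as.numeric(names(by_f))
  idx <- match(f, reference$frequency_hz)
  keep <- !is.na(idx)
  f <- f[keep]; by_f <- by_f[keep]; idx <- idx[keep]
  m <- vapply(by_f, mean, numeric(1))
  out <- data.frame(
    frequency_hz = f, n = vapply(by_f, length, integer(1)),
    study_mean_db = unname(m), reference_mean_db = reference$mean_db[idx],
    deviation_db = unname(m) - reference$mean_db[idx]
  )
  out$advisory <- abs(out$deviation_db) > threshold_db
  out$in_reference_ci <- out$study_mean_db >= reference$ci95_lo[idx] &
    out$study_mean_db <= reference$ci95_hi[idx]
  out <- out[order(out$frequency_hz), ]
  rownames(out) <- NULL
  attr(out, "threshold_db") <- threshold_db
  attr(out, "caveat") <- paste(
    "The reference CI of the mean is very narrow (large reference n); a small",
    "study's mean is unlikely to fall inside it even when the study population",
    "is perfectly normal. Use the deviation and the advisory threshold instead.")
  out
}

#' Impact of a single extreme measurement on a small study
#'
#' Quantifies how one measurement lying right at the edge of the reference
#' range shifts a study's mean and SD. The deterministic surrogate models a
#' study of n - 1 observations with mean mu and sample SD sigma plus one
#' observation at `mu + k2 * sigma`: the mean shifts by `k2 * sigma / n` and
#' the SD becomes `sqrt(sigma^2 * (n-2)/(n-1) + (k2 * sigma)^2 / n)`. The
#' Monte-Carlo mode draws the n - 1 observations from N(mu, sigma) and
#' reports expected shifts over many replicates; it is the cross-check for
#' the surrogate, which is a modeling choice, not an exact distributional
#' result.
#'
#' @param n Study size (>= 2).
#' @param sigma Population SD in dB (default 5.2, the reference data's
#'   approximate total SD).
#' @param p Tolerance proportion defining the edge (via k2).
#' @param alpha One minus the TI confidence.
#' @param k2 Tolerance factor; default computed from `reference_n`.
#' @param reference_n Sample size behind the reference range (default 366).
#' @param mode `"surrogate"` (closed form) or `"monte_carlo"`.
#' @param n_rep Monte-Carlo replicates (>= 1e4 recommended).
#' @param seed Seed for the Monte-Carlo mode.
#' @return An `impact_result` list: `n`, `p`, `k2`, `mean_shift_db`,
#'   `sd_change_db`, `model`.
#' @export
impact_of_extreme <- function(n, sigma = 5.2, p = 0.95, alpha = 0.05,
                              k2 = NULL, reference_n = 366,
                              mode = c("surrogate", "monte_carlo"),
                              n_rep = 10000, seed = 1L) {
  mode <- match.arg(mode)
  if (n < 2) stop("need n >= 2", call. = FALSE)
  if (is.null(k2)) k2 <- tolerance_factor(reference_n, p, alpha)
  if (mode == "surrogate") {
    mean_shift <- k2 * sigma / n
    sd_new <- sqrt(sigma^2 * (n - 2) / (n - 1) + (k2 * sigma)^2 / n)
    sd_change <- sd_new - sigma
  } else {
    set.seed(as.integer(seed))
    shifts <- numeric(n_rep)
    sd_changes <- numeric(n_rep)
    for (r in seq_len(n_rep)) {
      x <- c(stats::rnorm(n - 1, 0, sigma), k2 * sigma)
      shifts[r] <- mean(x)
      sd_changes[r] <- stats::sd(x) - sigma
    }
    mean_shift <- mean(shifts)
    sd_change <- mean(sd_changes)
  }
  structure(list(n = n, p = p, k2 = k2, mean_shift_db = mean_shift,
                 sd_change_db = sd_change, model = mode),
            class = "impact_result")
}

# pooled per-frequency SD implied by a reference's TI widths
reference_sigma <- function(reference, ti_p = 0.95) {
  ti <- ti_cols_for(reference, ti_p)
  if (is.null(ti)) return(NA_real_)
  n_ref <- attr(reference, "n_curves")
  if (is.na(n_ref)) n_ref <- 366
  k2 <- tolerance_factor(n_ref, ti_p, attr(reference, "alpha"))
  stats::median((ti$hi - ti$lo) / (2 * k2), na.rm = TRUE)
}

#' Aggregated guideline report for a study
#'
#' Applies the suggested-use protocol to a whole study: per-curve verdicts
#' against the reference range, study-mean comparison, a sample-size advisory
#' (strong warning below n = 5, soft warning below n = 10), and the
#' impact-of-extreme analysis at the study's n (using the SD implied by the
#' reference TI widths).
#'
#' @param study A `metf_table` in the reference's unit.
#' @param reference A `reference_table`.
#' @param ti_p Tolerance proportion for validation.
#' @param threshold_db Study-mean advisory threshold.
#' @return A `guideline_report` list: `n`, `sample_size_advisory`,
#'   `verdicts` (list of `validation_verdict`), `verdict_counts`,
#'   `mean_comparison`, `impact`, `notes`.
#' @export
guideline_report <- function(study, reference, ti_p = 0.95, threshold_db = 6) {
  study <- metf_table(study)
  curves <- table_to_curves(study)
  n <- length(curves)
  advisory <- if (n < 5) {
    sprintf("strong warning: only %d valid measurement(s); statistical analysis needs n >= 5", n)
  } else if (n < 10) {
    sprintf("soft warning: n = %d; n >= 10 is preferable for statistical analysis", n)
  } else {
    sprintf("sample size adequate (n = %d)", n)
  }
  verdicts <- lapply(curves, validate_curve, reference = reference, ti_p = ti_p)
  statuses <- vapply(verdicts, function(v) v$status, character(1))
  sigma <- reference_sigma(reference, ti_p)
  impact <- if (n >= 2 && is.finite(sigma)) {
    impact_of_extreme(n, sigma = sigma, p = ti_p, alpha = attr(reference, "alpha"))
  } else NULL
  notes <- character()
  if (any(statuses == "flagged")) {
    notes <- c(notes, paste(
      "flagged curves are reported, never auto-excluded: decide whether each",
      "reflects an undetected pathology, a measurement error, or an unusual",
      "but normal ear"))
  }
  structure(
    list(n = n, sample_size_advisory = advisory, verdicts = verdicts,
         verdict_counts = table(factor(statuses, levels = c(
           "valid", "valid_after_truncation", "flagged"))),
         mean_comparison = compare_study_mean(study, reference, threshold_db),
         impact = impact, notes = notes),
    class = "guideline_report"
  )
}

#' @export
print.guideline_report <- function(x, ...) {
  cat(sprintf("<guideline_report> n = %d curves\n", x$n))
  cat("  ", x$sample_size_advisory, "\n", sep = "")
  vc <- x$verdict_counts
  cat(sprintf("  verdicts: %d valid, %d valid after truncation, %d flagged\n",
              vc[["valid"]], vc[["valid_after_truncation"]], vc[["flagged"]]))
  mc <- x$mean_comparison
  cat(sprintf("  study-mean deviation: max |dev| %.1f dB, %d advisory frequency(ies)\n",
              max(abs(mc$deviation_db)), sum(mc$advisory)))
  if (!is.null(x$impact)) {
    cat(sprintf("  one edge measurement at this n shifts the mean by %.2f dB\n",
                x$impact$mean_shift_db))
  }
  for (n in x$notes) cat("  note:", n, "\n")
  invisible(x)
}
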