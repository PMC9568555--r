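# Per-frequency Tukey-fence outlier screening with the discard/truncate
# exclusion logic, and the two-pass (per-cell, then pooled method-A) screen.

#' Per-frequency Tukey fences
#'
#' Quartiles per frequency (linear interpolation of order statistics by
#' default, R quantile type 7) extended by a k-multiple of the IQR:
#' `lower = Q1 - k*IQR`, `upper = Q3 + k*IQR`. The screening default is
#' k = 1.75, a deliberately lenient multiplier for the slightly left-skewed
#' METF magnitude distributions (k = 1.5 is the usual choice for clean
#' normal data).
#'
#' @param table A `metf_table` with at least 4 values per frequency.
#' @param k Fence multiplier (> 0).
#' @param quantile_type Quantile convention (R types 1-9; default 7). Exposed
#'   because exclusion counts are sensitive to it.
#' @return A `fence_set` data frame: `frequency_hz, q1, q3, iqr, lower,
#'   upper`; attributes `k`, `quantile_type`.
#' @export
compute_fences <- function(table, k = 1.75, quantile_type = 7) {
  stopifnot(k > 0)
  table <- metf_table(table)
  by_f <- split(table$metf_db, table$frequency_hz)
  ns <- vapply(by_f, length, integer(1))
  if (any(ns < 4)) {
    stop(sprintf("need >= 4 values per frequency; too few at %s Hz",
                 paste(names(by_f)[ns < 4], collapse = ", ")), call. = FALSE)
  }
  q1 <- vapply(by_f, stats::quantile, numeric(1), probs = 0.25,
               type = quantile_type, names = FALSE)
  q3 <- vapply(by_f, stats::quantile, numeric(1), probs = 0.75,
               type = quantile_type, names = FALSE)
  out <- data.frame(frequency_hz = as.numeric(names(by_f)),
                    q1 = q1, q3 = q3, iqr = q3 - q1,
                    lower = q1 - k * (q3 - q1), upper = q3 + k * (q3 - q1))
  out <- out[order(out$frequency_hz), ]
  rownames(out) <- NULL
  structure(out, class = c("fence_set", "data.frame"),
            k = k, quantile_type = quantile_type)
}

#' Flag points outside the fences
#'
#' A point is an outlier iff its value lies strictly outside
#' `[lower, upper]`; values exactly on a fence are kept.
#'
#' @param table A `metf_table`.
#' @param fences A `fence_set` covering every frequency in the table.
#' @return Logical vector aligned with the table rows.
#' @export
flag_outliers <- function(table, fences) {
  stopifnot(inherits(fences, "fence_set"))
  idx <- match(table$frequency_hz, fences$frequency_hz)
  if (any(is.na(idx))) {
    stop(sprintf("no fences for frequency %s Hz",
                 paste(unique(table$frequency_hz[is.na(idx)]), collapse = ", ")),
         call. = FALSE)
  }
  table$metf_db < fences$lower[idx] | table$metf_db > fences$upper[idx]
}

#' Apply the discard/truncate exclusion rules
#'
#' A curve with any flagged point inside the core band (500-4000 Hz,
#' inclusive) is discarded entirely: a single outlier there may be part of a
#' wider peak biasing its neighbors. Curves flagged only at the spectral edges
#' are truncated at the most medial flagged frequency: all points at and
#' outward from the innermost flagged low (f < 500 Hz) or high (f > 4000 Hz)
#' frequency are removed; unflagged points more medial than that are kept.
#'
#' @param table A `metf_table`.
#' @param flags Logical vector from [flag_outliers()], aligned with the rows.
#' @param core_band_hz Inclusive discard band (default `c(500, 4000)`).
#' @return List with `table` (the screened `metf_table`) and `report` (an
#'   `exclusion_report` data frame: per curve `tb_id, group, method, verdict,
#'   offending_frequencies`; attribute `counts_by_group` = excluded curves per
#'   group).
#' @export
apply_exclusion_rules <- function(table, flags, core_band_hz = c(500, 4000)) {
  table <- metf_table(table)
  stopifnot(length(flags) == nrow(table))
  ids <- unique(table$tb_id)
  verdicts <- character(length(ids))
  offending <- character(length(ids))
  keep_row <- rep(TRUE, nrow(table))
  for (j in seq_along(ids)) {
    rows <- which(table$tb_id == ids[j])
    f <- table$frequency_hz[rows]
    fl <- flags[rows]
    bad <- f[fl]
    offending[j] <- paste(bad, collapse = ";")
    in_core <- bad >= core_band_hz[1] & bad <= core_band_hz[2]
    low <- bad[bad < core_band_hz[1]]
    high <- bad[bad > core_band_hz[2]]
    if (any(in_core)) {
      verdicts[j] <- "discard"
      keep_row[rows] <- FALSE
    } else if (length(low) > 0 || length(high) > 0) {
      verdicts[j] <- if (length(low) > 0 && length(high) > 0) "truncate_both"
                     else if (length(low) > 0) "truncate_low" else "truncate_high"
      drop <- rep(FALSE, length(rows))
      if (length(low) > 0) drop <- drop | f <= max(low)
      if (length(high) > 0) drop <- drop | f >= min(high)
      keep_row[rows[drop]] <- FALSE
    } else {
      verdicts[j] <- "keep"
    }
  }
  meta <- table[match(ids, table$tb_id), c("tb_id", "group", "method")]
  report <- data.frame(meta, verdict = verdicts, offending_frequencies = offending,
                       stringsAsFactors = FALSE)
  rownames(report) <- NULL
  discarded <- report$group[report$verdict == "discard"]
  counts <- if (length(discarded) > 0) table(discarded) else table(character())
  class(report) <- c("exclusion_report", "data.frame")
  attr(report, "counts_by_group") <- counts
  attr(report, "core_band_hz") <- core_band_hz
  list(table = metf_table(as.data.frame(table)[keep_row, , drop = FALSE]),
       report = report)
}

#' One screening pass (fences, flags, exclusion)
#'
#' @param table A `metf_table`.
#' @param k Fence multiplier.
#' @param core_band_hz Discard band.
#' @param quantile_type Quantile convention.
#' @return As [apply_exclusion_rules()], plus `fences`.
#' @export
screen_outliers <- function(table, k = 1.75, core_band_hz = c(500, 4000),
                            quantile_type = 7) {
  fences <- compute_fences(table, k = k, quantile_type = quantile_type)
  flags <- flag_outliers(table, fences)
  out <- apply_exclusion_rules(table, flags, core_band_hz = core_band_hz)
  out$fences <- fences
  out
}

#' Two-pass outlier screen
#'
#' Pass 1 screens within each (group, method) cell, so between-cell offsets do
#' not mask within-cell outliers; its survivors feed the group comparisons.
#' Pass 2 pools the method-"A" data into one combined set, recomputes fences
#' on the pooled values and screens again; its survivors feed the reference
#' construction. By default the two passes are independent branches (pass 2
#' starts from the raw method-A rows); `chain = TRUE` feeds pass-1 survivors
#' into pass 2 instead.
#'
#' Cells with fewer than 4 values at some frequency cannot support quartile
#' fences and are passed through unscreened with a warning.
#'
#' @param table A `metf_table` with group/method labels.
#' @param k Fence multiplier.
#' @param core_band_hz Discard band.
#' @param quantile_type Quantile convention.
#' @param chain Feed pass-1 survivors into pass 2? Default `FALSE`.
#' @param pooled_method Method label pooled in pass 2 (default `"A"`).
#' @return List: `by_cell` (pass-1 survivors as `metf_table`, plus
#'   `reports`, a per-cell list of exclusion reports) and `combined` (pass-2
#'   result: `table`, `report`, `fences`).
#' @export
two_pass_screen <- function(table, k = 1.75, core_band_hz = c(500, 4000),
                            quantile_type = 7, chain = FALSE,
                            pooled_method = "A") {
  table <- metf_table(table)
  cell <- interaction(table$group, table$method, drop = TRUE)
  pass1_tables <- list()
  pass1_reports <- list()
  for (lv in levels(cell)) {
    sub <- metf_table(as.data.frame(table)[cell == lv, , drop = FALSE])
    res <- tryCatch(
      screen_outliers(sub, k = k, core_band_hz = core_band_hz,
                      quantile_type = quantile_type),
      error = function(e) {
        warning(sprintf("cell %s too small for fences; passed through (%s)",
                        lv, conditionMessage(e)), call. = FALSE)
        list(table = sub, report = NULL)
      }
    )
    pass1_tables[[lv]] <- as.data.frame(res$table)
    pass1_reports[[lv]] <- res$report
    metfref_log("pass 1 [%s]: %d -> %d rows", lv, nrow(sub), nrow(res$table))
  }
  pass1 <- metf_table(do.call(rbind, pass1_tables))
  src <- if (chain) pass1 else table
  pooled <- metf_table(as.data.frame(src)[src$method == pooled_method, , drop = FALSE])
  if (nrow(pooled) == 0) {
    stop(sprintf("no rows with method '%s' to pool in pass 2", pooled_method),
         call. = FALSE)
  }
  combined <- screen_outliers(pooled, k = k, core_band_hz = core_band_hz,
                              quantile_type = quantile_type)
  metfref_log("pass 2 [pooled %s]: %d -> %d rows", pooled_method,
              nrow(pooled), nrow(combined$table))
  list(by_cell = list(table = pass1, reports = pass1_reports),
       combined = combined)
}
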