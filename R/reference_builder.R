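# Per-frequency reference construction: mean, 95% CI of the mean, and
# two-sided (p, 1 - alpha) normal tolerance intervals.

#' Confidence interval of the mean
#'
#' `xbar +/- t_{1-alpha/2, n-1} * s / sqrt(n)`.
#'
#' @param values Numeric vector, n >= 2.
#' @param alpha Type-I error level (default 0.05 -> 95% CI).
#' @return Numeric `c(lo, hi)`.
#' @export
ci_mean <- function(values, alpha = 0.05) {
  n <- length(values)
  if (n < 2) stop("need n >= 2 for a CI of the mean", call. = FALSE)
  m <- mean(values)
  half <- stats::qt(1 - alpha / 2, n - 1) * stats::sd(values) / sqrt(n)
  c(lo = m - half, hi = m + half)
}

#' Two-sided normal tolerance factor k2
#'
#' Factor such that `xbar +/- k2 * s` contains at least a proportion `p` of a
#' normal population with confidence `1 - alpha`.
#'
#' `method = "howe"` uses Howe's closed-form approximation
#' `k2 = z_{(1+p)/2} * sqrt(nu * (1 + 1/n) / chisq_{nu, alpha})` with
#' `nu = n - 1` and the lower-alpha chi-square quantile. `method = "exact"`
#' solves the exact two-sided condition numerically: the confidence of the
#' interval is
#' `integral over the sampling distribution of the sample mean of
#'  P(chi2_nu >= nu * r(u)^2 / k2^2)`, where `r(u)` is the half-width (in SD
#' units) of the interval centered at `u` containing probability `p`.
#' Both are deterministic; `n = Inf` returns the normal quantile limit.
#'
#' @param n Sample size (>= 2, or `Inf`).
#' @param p Population proportion in (0, 1).
#' @param alpha One minus the confidence level, in (0, 1).
#' @param method `"howe"` (default) or `"exact"`.
#' @return The factor k2 (> 0). Decreasing in n, increasing in p and in
#'   confidence.
#' @export
#' @examples
#' tolerance_factor(20, 0.95, 0.05)          # ~2.752
#' tolerance_factor(Inf, 0.95, 0.05)         # 1.960
tolerance_factor <- function(n, p = 0.95, alpha = 0.05,
                             method = c("howe", "exact")) {
  method <- match.arg(method)
  stopifnot(p > 0, p < 1, alpha > 0, alpha < 1)
  z <- stats::qnorm((1 + p) / 2)
  if (is.infinite(n)) return(z)
  if (n < 2) stop("need n >= 2 for a tolerance factor", call. = FALSE)
  nu <- n - 1
  if (method == "howe") {
    return(z * sqrt(nu * (1 + 1 / n) / stats::qchisq(alpha, nu)))
  }
  # exact: content of xbar +/- k*S exceeds p iff S/sigma >= r(u)/k, where
  # u = (xbar - mu)/sigma ~ N(0, 1/n) and Phi(u + r) - Phi(u - r) = p
  r_of_u <- function(u) {
    vapply(u, function(ui) {
      stats::uniroot(function(r) stats::pnorm(ui + r) - stats::pnorm(ui - r) - p,
                     lower = z * 0.5, upper = z + abs(ui) + 10,
                     tol = 1e-10)$root
    }, numeric(1))
  }
  confidence <- function(k) {
    integrand <- function(u) {
      2 * sqrt(n) * stats::dnorm(sqrt(n) * u) *
        stats::pchisq(nu * r_of_u(u)^2 / k^2, nu, lower.tail = FALSE)
    }
    stats::integrate(integrand, 0, 10 / sqrt(n), rel.tol = 1e-9)$value
  }
  howe <- z * sqrt(nu * (1 + 1 / n) / stats::qchisq(alpha, nu))
  stats::uniroot(function(k) confidence(k) - (1 - alpha),
                 lower = howe * 0.7, upper = howe * 1.3, tol = 1e-8)$root
}

#' Two-sided tolerance interval
#'
#' `xbar +/- k2(n, p, alpha) * s`, the interval containing proportion p of
#' the population with confidence 1 - alpha.
#'
#' @param values Numeric vector, n >= 2.
#' @param p Population proportion.
#' @param alpha One minus the confidence level.
#' @param method Passed to [tolerance_factor()].
#' @return Numeric `c(lo, hi)`.
#' @export
tolerance_interval <- function(values, p = 0.95, alpha = 0.05, method = "howe") {
  n <- length(values)
  if (n < 2) stop("need n >= 2 for a tolerance interval", call. = FALSE)
  k2 <- tolerance_factor(n, p, alpha, method)
  m <- mean(values)
  s <- stats::sd(values)
  c(lo = m - k2 * s, hi = m + k2 * s)
}

#' Build a reference table from a screened METF table
#'
#' Per frequency: n, mean, CI of the mean, and two-sided tolerance intervals
#' for the configured proportions (computed independently per frequency, no
#' cross-frequency pooling). Frequencies with fewer than `min_n` values are
#' skipped with a warning. Normality of the per-frequency dB values is
#' assumed (use [moments()] to check skewness/kurtosis first).
#'
#' @param table A screened (post-outlier) `metf_table` in one unit.
#' @param ti_p Tolerance proportions; any subset of `c(0.90, 0.95, 0.99)`
#'   (the table schema carries these three columns).
#' @param alpha One minus the confidence level (applies to CI and TIs).
#' @param method Tolerance-factor method (`"howe"` or `"exact"`).
#' @param min_n Minimum values per frequency (default 4).
#' @return A `reference_table` for the table's unit, with `n_curves` /
#'   `n_points` metadata.
#' @export
build_reference <- function(table, ti_p = c(0.90, 0.95, 0.99), alpha = 0.05,
                            method = "howe", min_n = 4) {
  table <- metf_table(table)
  stopifnot(nrow(table) > 0)
  if (length(unique(table$unit)) != 1) {
    stop("table must hold a single unit", call. = FALSE)
  }
  allowed <- c(0.90, 0.95, 0.99)
  if (!all(ti_p %in% allowed)) {
    stop("ti_p must be a subset of {0.90, 0.95, 0.99}", call. = FALSE)
  }
  by_f <- split(table$metf_db, table$frequency_hz)
  rows <- list()
  for (fstr in names(by_f)) {
    v <- by_f[[fstr]]
    if (length(v) < min_n) {
      warning(sprintf("skipping %s Hz: only %d values (< %d)",
                      fstr, length(v), min_n), call. = FALSE)
      next
    }
    ci <- ci_mean(v, alpha)
    row <- data.frame(unit = table$unit[1], frequency_hz = as.numeric(fstr),
                      n = length(v), mean_db = mean(v),
                      ci95_lo = ci[["lo"]], ci95_hi = ci[["hi"]],
                      ti90_lo = NA_real_, ti90_hi = NA_real_,
                      ti95_lo = NA_real_, ti95_hi = NA_real_,
                      ti99_lo = NA_real_, ti99_hi = NA_real_,
                      stringsAsFactors = FALSE)
    for (p in ti_p) {
      ti <- tolerance_interval(v, p, alpha, method)
      tag <- sprintf("%02d", round(100 * p))
      row[[paste0("ti", tag, "_lo")]] <- ti[["lo"]]
      row[[paste0("ti", tag, "_hi")]] <- ti[["hi"]]
    }
    rows[[fstr]] <- row
  }
  if (length(rows) == 0) stop("no frequency had enough values", call. = FALSE)
  reference_table(do.call(rbind, rows), alpha = alpha,
                  n_curves = length(unique(table$tb_id)), n_points = nrow(table))
}

#' Convert a reference table between units
#'
#' Applies the exact per-frequency offset `+/- 20*log10(2*pi*f)` to every
#' statistic (mean, CI and TI bounds); the conversion is affine per
#' frequency, so the converted table equals the table that would have been
#' built directly from converted data.
#'
#' @param reference A `reference_table`.
#' @param target_unit `"displacement"` or `"velocity"` (must differ).
#' @return The converted `reference_table`.
#' @export
convert_reference <- function(reference, target_unit) {
  stopifnot(inherits(reference, "reference_table"))
  target_unit <- match.arg(target_unit, metf_units)
  if (any(reference$unit == target_unit)) {
    stop("reference is already in the target unit", call. = FALSE)
  }
  offset <- velocity_offset_db(reference$frequency_hz)
  if (target_unit == "displacement") offset <- -offset
  out <- as.data.frame(reference)
  for (col in c("mean_db", "ci95_lo", "ci95_hi", "ti90_lo", "ti90_hi",
                "ti95_lo", "ti95_hi", "ti99_lo", "ti99_hi")) {
    out[[col]] <- out[[col]] + offset
  }
  out$unit <- target_unit
  reference_table(out, alpha = attr(reference, "alpha"),
                  n_curves = attr(reference, "n_curves"),
                  n_points = attr(reference, "n_points"))
}
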