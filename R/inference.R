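# Group comparisons (Welch t-tests, Holm adjustment), distribution moments,
# and the crossed random-effects variance decomposition with
# Nakagawa-Schielzeth R-squared.

#' Welch two-sample t-test
#'
#' Unequal-variance t-test with Welch-Satterthwaite degrees of freedom,
#' two-sided. Chosen over the pooled test because the METF data sets are
#' heteroscedastic across laboratories.
#'
#' @param sample_a,sample_b Numeric vectors, each with n >= 2; at least one
#'   must have nonzero variance.
#' @return List: `t`, `df`, `p` (two-sided), `mean_diff` (mean(a) - mean(b)).
#' @export
welch_t <- function(sample_a, sample_b) {
  if (length(sample_a) < 2 || length(sample_b) < 2) {
    stop("each sample needs n >= 2", call. = FALSE)
  }
  if (stats::var(sample_a) == 0 && stats::var(sample_b) == 0) {
    stop("both samples are constant (degenerate)", call. = FALSE)
  }
  ht <- stats::t.test(sample_a, sample_b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, mean_diff = mean(sample_a) - mean(sample_b))
}

#' Holm step-down p-value adjustment
#'
#' Sequentially rejective correction controlling the family-wise error rate:
#' sorted ascending, `p_(i)` is multiplied by `(m - i + 1)`, running maxima
#' enforced, capped at 1, returned in the original order.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same order; always elementwise <= Bonferroni.
#' @export
holm_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1 | !is.finite(p_values))) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "holm")
}

#' All pairwise Welch comparisons at each frequency
#'
#' Tests every pair of factor levels at every frequency; Holm adjustment is
#' applied within one frequency (the family is the set of pairwise tests at
#' that frequency; `family = "global"` pools all frequencies instead).
#' Levels with fewer than 2 observations at a frequency are skipped with a
#' warning.
#'
#' @param table A `metf_table`.
#' @param factor `"group"` or `"method"`.
#' @param alpha Significance level for the `significant` flag.
#' @param family Holm family scope: `"frequency"` (default) or `"global"`.
#' @return Data frame of `pairwise_comparison` rows: `frequency_hz, level_a,
#'   level_b, n_a, n_b, mean_diff_db, t, df, p, p_adj, significant`.
#' @export
pairwise_by_frequency <- function(table, factor = c("group", "method"),
                                  alpha = 0.05, family = c("frequency", "global")) {
  factor <- match.arg(factor)
  family <- match.arg(family)
  table <- metf_table(table)
  fac <- table[[factor]]
  rows <- list()
  skipped <- character()
  for (f in sort(unique(table$frequency_hz))) {
    sel <- table$frequency_hz == f
    vals <- split(table$metf_db[sel], fac[sel])
    small <- names(vals)[vapply(vals, length, integer(1)) < 2]
    if (length(small) > 0) {
      skipped <- union(skipped, sprintf("%s @ %g Hz", small, f))
      vals <- vals[!(names(vals) %in% small)]
    }
    lv <- names(vals)
    if (length(lv) < 2) next
    for (i in seq_len(length(lv) - 1)) {
      for (j in (i + 1):length(lv)) {
        wt <- welch_t(vals[[i]], vals[[j]])
        rows[[length(rows) + 1]] <- data.frame(
          frequency_hz = f, level_a = lv[i], level_b = lv[j],
          n_a = length(vals[[i]]), n_b = length(vals[[j]]),
          mean_diff_db = wt$mean_diff, t = wt$t, df = wt$df, p = wt$p,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(skipped) > 0) {
    warning(sprintf("skipped levels with n < 2: %s",
                    paste(skipped, collapse = ", ")), call. = FALSE)
  }
  if (length(rows) == 0) {
    return(data.frame(frequency_hz = numeric(), level_a = character(),
                      level_b = character(), n_a = integer(), n_b = integer(),
                      mean_diff_db = numeric(), t = numeric(), df = numeric(),
                      p = numeric(), p_adj = numeric(), significant = logical(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out$p_adj <- if (family == "global") holm_adjust(out$p) else {
    stats::ave(out$p, out$frequency_hz, FUN = holm_adjust)
  }
  out$significant <- out$p_adj < alpha
  out
}

#' Sample skewness and kurtosis
#'
#' Adjusted Fisher-Pearson sample skewness and sample excess kurtosis (both
#' bias-adjusted, e1071 type 2 - the convention of common statistical
#' software). The raw kurtosis (excess + 3) is also reported because "kurtosis
#' < 2" style normality screens are stated ambiguously in the literature.
#'
#' @param values Numeric vector, n >= 4.
#' @return List `skewness`, `kurtosis_excess`, `kurtosis_raw`; attribute
#'   `convention`.
#' @export
moments <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 4) stop("need n >= 4 for moments", call. = FALSE)
  out <- list(skewness = e1071::skewness(values, type = 2),
              kurtosis_excess = e1071::kurtosis(values, type = 2),
              kurtosis_raw = e1071::kurtosis(values, type = 2) + 3)
  attr(out, "convention") <- "adjusted Fisher-Pearson (type 2); excess kurtosis"
  out
}

#' Crossed random-effects variance decomposition
#'
#' Fits, by REML, a linear mixed model with a polynomial fixed effect in
#' standardized log10-frequency and crossed random intercepts for specimen
#' (`tb_id`), measurement method and research group:
#' `metf_db ~ poly(z, order) + (1|tb_id) + (1|method) + (1|group)`.
#' Random factors with a single level in the data are dropped with a warning
#' and reported with variance 0. Singular fits (a variance estimated at the
#' zero boundary) are reported as such, not errors.
#'
#' @param table A `metf_table`.
#' @param poly_order Order of the fixed polynomial (default 3; the typical
#'   METF shape - resonance near 1 kHz, roll-off above - is cubic-like in log
#'   frequency).
#' @param reml Use REML (default) or ML.
#' @return A `variance_decomposition` list: `coefficients` (raw polynomial
#'   coefficients on the z scale), `sigma2` (named: tb, method, group, resid,
#'   in dB^2), `sd` (their square roots), `sigma2_fixed` (population variance
#'   of the fixed-effect predictions), `r2_marginal`, `r2_conditional`,
#'   `loglik`, `converged`, `singular`, `n_obs`, `poly_order`, `center`,
#'   `scale`, `criterion`.
#' @export
fit_lmm <- function(table, poly_order = 3, reml = TRUE) {
  table <- metf_table(table)
  lf <- log10(unique(table$frequency_hz))
  if (length(lf) < poly_order + 1) {
    stop("not enough distinct frequencies for the requested polynomial order",
         call. = FALSE)
  }
  center <- mean(lf)
  scale <- stats::sd(lf)
  d <- data.frame(y = table$metf_db,
                  z = (log10(table$frequency_hz) - center) / scale,
                  tb_id = table$tb_id, method = table$method,
                  group = table$group, stringsAsFactors = FALSE)
  re_terms <- c(tb = "tb_id", method = "method", group = "group")
  use <- vapply(re_terms, function(v) length(unique(d[[v]])) >= 2, logical(1))
  if (any(!use)) {
    warning(sprintf("random factor(s) with a single level dropped: %s",
                    paste(names(re_terms)[!use], collapse = ", ")), call. = FALSE)
  }
  if (!any(use)) stop("no random factor has >= 2 levels", call. = FALSE)
  form <- stats::as.formula(paste(
    "y ~ poly(z,", poly_order, ", raw = TRUE) +",
    paste(sprintf("(1 | %s)", re_terms[use]), collapse = " + ")
  ))
  fit <- lme4::lmer(form, data = d, REML = reml)
  conv_msgs <- unlist(fit@optinfo$conv$lme4$messages)
  conv_msgs <- conv_msgs[!grepl("singular", conv_msgs)]  # boundary != failure
  converged <- length(conv_msgs) == 0
  if (!converged) {
    warning(sprintf("mixed-model fit did not cleanly converge: %s",
                    paste(unlist(conv_msgs), collapse = "; ")), call. = FALSE)
  }
  vc <- as.data.frame(lme4::VarCorr(fit))
  sigma2 <- c(tb = 0, method = 0, group = 0, resid = stats::sigma(fit)^2)
  for (nm in names(re_terms)[use]) {
    v <- vc$vcov[vc$grp == re_terms[nm]]
    if (length(v) == 1) sigma2[nm] <- v
  }
  pred_fixed <- stats::predict(fit, re.form = NA)
  sigma2_fixed <- mean((pred_fixed - mean(pred_fixed))^2)
  r2 <- r2_nakagawa(sigma2_fixed, sigma2[c("tb", "method", "group")], sigma2["resid"])
  structure(
    list(coefficients = unname(lme4::fixef(fit)), sigma2 = sigma2,
         sd = sqrt(sigma2), sigma2_fixed = sigma2_fixed,
         r2_marginal = r2[["marginal"]], r2_conditional = r2[["conditional"]],
         loglik = as.numeric(stats::logLik(fit)), converged = converged,
         singular = lme4::isSingular(fit), n_obs = nrow(d),
         poly_order = poly_order, center = center, scale = scale,
         criterion = if (reml) "REML" else "ML"),
    class = "variance_decomposition"
  )
}

#' @export
print.variance_decomposition <- function(x, ...) {
  cat(sprintf("<variance_decomposition> %s, poly order %d, n = %d\n",
              x$criterion, x$poly_order, x$n_obs))
  cat(sprintf("  SD (dB): tb %.2f | method %.2f | group %.2f | resid %.2f\n",
              x$sd["tb"], x$sd["method"], x$sd["group"], x$sd["resid"]))
  cat(sprintf("  R2 marginal %.1f%% | conditional %.1f%%%s%s\n",
              100 * x$r2_marginal, 100 * x$r2_conditional,
              if (x$singular) " | singular" else "",
              if (!x$converged) " | NOT CONVERGED" else ""))
  invisible(x)
}

#' Nakagawa-Schielzeth R-squared for mixed models
#'
#' `R2_marginal = s2_f / (s2_f + sum(s2_random) + s2_resid)` (fixed effects
#' only) and `R2_conditional = (s2_f + sum(s2_random)) / (same denominator)`
#' (fixed plus random), where `s2_f` is the population variance of the
#' fixed-effect predictions over the observed design.
#'
#' @param sigma2_fixed Variance of the fixed-effect predictions, or a
#'   `variance_decomposition` (then the other arguments are ignored).
#' @param sigma2_random Vector of random-intercept variances.
#' @param sigma2_resid Residual variance.
#' @return Named vector `marginal`, `conditional` (both in `[0, 1]`,
#'   marginal <= conditional).
#' @export
r2_nakagawa <- function(sigma2_fixed, sigma2_random = NULL, sigma2_resid = NULL) {
  if (inherits(sigma2_fixed, "variance_decomposition")) {
    d <- sigma2_fixed
    sigma2_random <- d$sigma2[c("tb", "method", "group")]
    sigma2_resid <- d$sigma2[["resid"]]
    sigma2_fixed <- d$sigma2_fixed
  }
  sigma2_fixed <- unname(sigma2_fixed)
  sigma2_resid <- unname(sigma2_resid)
  stopifnot(sigma2_fixed >= 0, all(sigma2_random >= 0), sigma2_resid >= 0)
  denom <- sigma2_fixed + sum(sigma2_random) + sigma2_resid
  if (denom == 0) stop("all variance components are zero (degenerate)", call. = FALSE)
  c(marginal = sigma2_fixed / denom,
    conditional = (sigma2_fixed + sum(sigma2_random)) / denom)
}
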