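# Seeded synthetic METF populations with the statistical structure the
# analysis assumes: cubic-in-log-frequency mean curve, crossed random
# intercepts for specimen / measurement method / research group, i.i.d.
# residual noise with an optional variance-preserving left skew.

#' Fit the cubic mean curve of a reference table
#'
#' Least-squares cubic in standardized log10-frequency through the reference
#' means. The covariate is `z = (log10 f - center) / scale` with center/scale
#' taken over the reference grid, keeping the cubic well-conditioned.
#'
#' @param reference A `reference_table` (single unit) with >= 4 frequencies.
#' @return List: `coefficients` (beta0..beta3 on the z scale), `residuals`
#'   (per-frequency, dB), `center`, `scale`, `frequencies_hz`, `unit`.
#' @export
fit_mean_curve <- function(reference) {
  stopifnot(inherits(reference, "reference_table"))
  if (length(unique(reference$unit)) != 1) {
    stop("reference must hold a single unit", call. = FALSE)
  }
  f <- reference$frequency_hz
  y <- reference$mean_db
  if (length(f) < 4) stop("need >= 4 frequencies to fit a cubic", call. = FALSE)
  lf <- log10(f)
  center <- mean(lf)
  scale <- stats::sd(lf)
  z <- (lf - center) / scale
  fit <- stats::lm(y ~ z + I(z^2) + I(z^3))
  beta <- unname(stats::coef(fit))
  list(coefficients = beta, residuals = unname(stats::residuals(fit)),
       center = center, scale = scale, frequencies_hz = f,
       unit = reference$unit[1])
}

# evaluate a cubic mean curve (as returned by fit_mean_curve) at frequencies
eval_mean_curve <- function(curve, frequency_hz) {
  z <- (log10(frequency_hz) - curve$center) / curve$scale
  curve$coefficients[1] + curve$coefficients[2] * z +
    curve$coefficients[3] * z^2 + curve$coefficients[4] * z^3
}

#' Synthetic population specification
#'
#' The generator's defaults encode the reference study's structure: random
#' intercept SDs of 4.2 dB (specimen), 3.4 dB (measurement method) and 1.4 dB
#' (research group); residual SD 3.0 dB (so total SD ~ 5.4 dB, consistent
#' with the ~10.4 dB 95% TI half-width at 1 kHz divided by the large-n
#' two-sided tolerance factor ~ 2.0); a cubic mean curve fitted to the
#' packaged displacement reference; and a default design of 4 research groups
#' x 1 method x 100 specimens per cell, mirroring the scale of the pooled
#' single-point-LDV data set the reference was built from.
#'
#' @param n_groups,n_methods,n_tb_per_cell Fully crossed design dimensions.
#' @param sigma_tb,sigma_method,sigma_group,sigma_resid Random-effect and
#'   residual SDs in dB (>= 0).
#' @param mean_curve Cubic mean curve (as from [fit_mean_curve()]); default
#'   the packaged displacement reference fit.
#' @param skew_shape Skew-normal shape for the residuals (0 = Gaussian;
#'   negative = left skew; variance preserved).
#' @param grid Frequency grid (default audiological).
#' @param seed Master integer seed.
#' @return A `population_spec` list.
#' @export
population_spec <- function(n_groups = 4, n_methods = 1, n_tb_per_cell = 100,
                            sigma_tb = 4.2, sigma_method = 3.4,
                            sigma_group = 1.4, sigma_resid = 3.0,
                            mean_curve = NULL, skew_shape = 0,
                            grid = audiological_grid(), seed = 1L) {
  stopifnot(n_groups >= 1, n_methods >= 1, n_tb_per_cell >= 1,
            sigma_tb >= 0, sigma_method >= 0, sigma_group >= 0, sigma_resid >= 0)
  validate_grid(grid)
  if (is.null(mean_curve)) {
    mean_curve <- fit_mean_curve(packaged_reference("displacement"))
  }
  structure(
    list(n_groups = as.integer(n_groups), n_methods = as.integer(n_methods),
         n_tb_per_cell = as.integer(n_tb_per_cell),
         sigma_tb = sigma_tb, sigma_method = sigma_method,
         sigma_group = sigma_group, sigma_resid = sigma_resid,
         mean_curve = mean_curve, skew_shape = skew_shape,
         grid = as.numeric(grid), seed = as.integer(seed)),
    class = "population_spec"
  )
}

# sub-seed derivation: one stream per entity class, offset per cell, so that
# e.g. the group draws do not move when specimens are added
derive_seed <- function(seed, stream, index = 0L) {
  as.integer((as.numeric(seed) * 7919 + stream * 104729 + index * 1299709) %%
               .Machine$integer.max)
}

# standardized skew-normal draws: mean 0, variance 1, shape alpha
rskewnorm_std <- function(n, alpha) {
  if (alpha == 0) return(stats::rnorm(n))
  delta <- alpha / sqrt(1 + alpha^2)
  z <- delta * abs(stats::rnorm(n)) + sqrt(1 - delta^2) * stats::rnorm(n)
  (z - delta * sqrt(2 / pi)) / sqrt(1 - 2 * delta^2 / pi)
}

#' Sample a synthetic METF population
#'
#' Draws `y(tb, f) = mean_curve(f) + u_group + u_method + u_tb + eps(tb, f)`
#' with crossed random intercepts (one draw per factor level, shared across
#' cells) and i.i.d. residuals, optionally left-skewed via a
#' variance-preserving skew-normal transform of the residuals only (the
#' intercepts stay Gaussian). Fully deterministic given the spec's seed, with
#' one RNG stream per entity class.
#'
#' @param spec A [population_spec()].
#' @param design Optional data frame `group, method` (one row per cell, with
#'   optional `n_tb` per cell) overriding the default full crossing; levels
#'   may repeat across rows to build sparse crossed designs.
#' @return List with `table` (a `metf_table`, unit displacement) and `truth`:
#'   `intercepts` (per specimen: realized `u_group`, `u_method`, `u_tb`),
#'   `points` (per point: the noise-free value `true_db` and the fixed-effect
#'   value `mean_db`), and the per-level draws.
#' @export
sample_population <- function(spec, design = NULL) {
  stopifnot(inherits(spec, "population_spec"))
  if (is.null(design)) {
    method_labels <- if (spec$n_methods <= 26) LETTERS[seq_len(spec$n_methods)]
                     else sprintf("M%02d", seq_len(spec$n_methods))
    design <- expand.grid(group = sprintf("G%02d", seq_len(spec$n_groups)),
                          method = method_labels,
                          stringsAsFactors = FALSE)
  }
  stopifnot(all(c("group", "method") %in% names(design)))
  if (is.null(design$n_tb)) design$n_tb <- spec$n_tb_per_cell
  groups <- sort(unique(design$group))
  methods <- sort(unique(design$method))

  set.seed(derive_seed(spec$seed, 1L))
  u_group <- stats::setNames(stats::rnorm(length(groups), 0, spec$sigma_group), groups)
  set.seed(derive_seed(spec$seed, 2L))
  u_method <- stats::setNames(stats::rnorm(length(methods), 0, spec$sigma_method), methods)

  mu <- eval_mean_curve(spec$mean_curve, spec$grid)
  nf <- length(spec$grid)
  rows <- vector("list", nrow(design))
  truth_rows <- vector("list", nrow(design))
  tb_counter <- 0L
  for (ci in seq_len(nrow(design))) {
    n_tb <- design$n_tb[ci]
    set.seed(derive_seed(spec$seed, 3L, ci))
    u_tb <- stats::rnorm(n_tb, 0, spec$sigma_tb)
    set.seed(derive_seed(spec$seed, 4L, ci))
    eps <- spec$sigma_resid * rskewnorm_std(n_tb * nf, spec$skew_shape)
    tb_ids <- sprintf("TB%05d", tb_counter + seq_len(n_tb))
    tb_counter <- tb_counter + n_tb
    base <- rep(mu, times = n_tb) + u_group[design$group[ci]] +
      u_method[design$method[ci]] + rep(u_tb, each = nf)
    rows[[ci]] <- data.frame(
      tb_id = rep(tb_ids, each = nf), group = design$group[ci],
      method = design$method[ci], frequency_hz = rep(spec$grid, times = n_tb),
      metf_db = base + eps, unit = "displacement", angle_deg = NA_real_,
      angle_corrected = FALSE, true_db = base,
      mean_db = rep(mu, times = n_tb), stringsAsFactors = FALSE
    )
    truth_rows[[ci]] <- data.frame(
      tb_id = tb_ids, group = design$group[ci], method = design$method[ci],
      u_group = unname(u_group[design$group[ci]]),
      u_method = unname(u_method[design$method[ci]]),
      u_tb = u_tb, stringsAsFactors = FALSE
    )
  }
  all_rows <- do.call(rbind, rows)
  table <- metf_table(all_rows[, metf_columns])
  points <- all_rows[order(all_rows$tb_id, all_rows$frequency_hz),
                     c("tb_id", "frequency_hz", "true_db", "mean_db")]
  rownames(points) <- NULL
  list(table = table,
       truth = list(intercepts = do.call(rbind, truth_rows), points = points,
                    u_group = u_group, u_method = u_method))
}

#' Adversarial outlier fixtures with an expected-verdict manifest
#'
#' Appends to a clean base population three pathological curves built from
#' the specimen closest to the per-frequency medians: one displaced +30 dB at
#' 2 kHz only (expected verdict: discard - the outlier sits in the core
#' band), one displaced -30 dB at 6 kHz only (expected: truncate_high), one
#' displaced +30 dB at 125 Hz only (expected: truncate_low). The same
#' near-median specimen is recorded with expected verdict keep.
#'
#' @param base A clean `metf_table` on the audiological grid.
#' @param seed Unused draw reserve (fixtures are deterministic); kept for
#'   interface stability.
#' @return List with `table` (base plus injected curves) and `manifest`
#'   (data frame `tb_id, expected_verdict`).
#' @export
make_outlier_fixtures <- function(base, seed = 1L) {
  base <- metf_table(base)
  stopifnot(nrow(base) > 0)
  med <- tapply(base$metf_db, base$frequency_hz, stats::median)
  # specimen closest to the median curve -> guaranteed keep
  dev_by_tb <- tapply(seq_len(nrow(base)), base$tb_id, function(i) {
    max(abs(base$metf_db[i] - med[as.character(base$frequency_hz[i])]))
  })
  anchor_id <- names(which.min(dev_by_tb))
  anchor <- as.data.frame(base)[base$tb_id == anchor_id, , drop = FALSE]
  inject <- function(new_id, at_hz, delta_db) {
    d <- anchor
    d$tb_id <- new_id
    hit <- d$frequency_hz == at_hz
    stopifnot(any(hit))
    d$metf_db[hit] <- d$metf_db[hit] + delta_db
    d
  }
  out <- rbind(as.data.frame(base),
               inject("OUT_DISCARD", 2000, +30),
               inject("OUT_TRUNC_HIGH", 6000, -30),
               inject("OUT_TRUNC_LOW", 125, +30))
  manifest <- data.frame(
    tb_id = c("OUT_DISCARD", "OUT_TRUNC_HIGH", "OUT_TRUNC_LOW", anchor_id),
    expected_verdict = c("discard", "truncate_high", "truncate_low", "keep"),
    stringsAsFactors = FALSE
  )
  list(table = metf_table(out), manifest = manifest)
}
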