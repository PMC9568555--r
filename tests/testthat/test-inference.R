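test_that("Welch t-test matches hand computation and is antisymmetric", {
  wt <- welch_t(c(1, 2, 3, 4, 5), c(3, 4, 5, 6, 7))
  expect_equal(wt$t, -2, tolerance = 1e-12)
  expect_equal(wt$df, 8, tolerance = 1e-12)  # equal variances -> df exactly 8
  expect_equal(wt$p, 0.0805, tolerance = 1e-3)
  expect_equal(wt$mean_diff, -2)
  rev <- welch_t(c(3, 4, 5, 6, 7), c(1, 2, 3, 4, 5))
  expect_equal(rev$t, -wt$t)
  expect_equal(rev$p, wt$p)
  same <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_error(welch_t(1, c(1, 2)), "n >= 2")
  expect_error(welch_t(c(2, 2), c(3, 3)), "degenerate")
})

test_that("Holm adjustment matches the step-down formula and dominates Bonferroni", {
  expect_equal(holm_adjust(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  expect_equal(holm_adjust(0.2), 0.2)
  expect_equal(holm_adjust(rep(1, 5)), rep(1, 5))
  expect_error(holm_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(4)
  for (i in 1:20) {
    p <- runif(sample(2:12, 1))
    adj <- holm_adjust(p)
    expect_true(all(adj >= p))
    expect_true(all(adj <= pmin(1, length(p) * p)))  # never above Bonferroni
    # permutation invariance
    perm <- sample(length(p))
    expect_equal(holm_adjust(p[perm]), adj[perm])
  }
})

test_that("pairwise comparisons detect large offsets and respect families", {
  grid <- audiological_grid()
  set.seed(5)
  mk <- function(prefix, grp, mu) do.call(rbind, lapply(1:30, function(i)
    data.frame(tb_id = sprintf("%s%02d", prefix, i), group = grp, method = "A",
               frequency_hz = grid, metf_db = mu + rnorm(8, 0, 4),
               unit = "displacement")))
  tb <- metf_table(rbind(mk("A", "G1", 0), mk("B", "G2", 10)))
  cmp <- pairwise_by_frequency(tb, "group")
  expect_equal(nrow(cmp), 8)  # one pair per frequency
  expect_true(all(cmp$significant))  # power ~1 at 10 dB / 4 dB / n=30
  expect_true(all(abs(cmp$mean_diff_db + 10) < 4))
  expect_true(all(cmp$p_adj >= cmp$p))
  # single level: empty result with a warning
  solo <- metf_table(mk("C", "G1", 0))
  expect_equal(nrow(suppressWarnings(pairwise_by_frequency(solo, "group"))), 0)
  # small level skipped with warning
  tiny <- metf_table(rbind(mk("A", "G1", 0),
                           data.frame(tb_id = "X01", group = "G3", method = "A",
                                      frequency_hz = grid, metf_db = 0,
                                      unit = "displacement")))
  expect_warning(pairwise_by_frequency(tiny, "group"), "n < 2")
})

test_that("null pairwise pipeline keeps its type-I rate near alpha", {
  set.seed(3)
  rej <- replicate(400, {
    tb <- values_table(rnorm(20, 0, 4))
    tb$group <- rep(c("G1", "G2"), each = 10)
    pairwise_by_frequency(metf_table(as.data.frame(tb)), "group")$p_adj < 0.05
  })
  expect_gt(mean(rej), 0.02)
  expect_lt(mean(rej), 0.09)
})

test_that("moments use the adjusted Fisher-Pearson / excess conventions", {
  mo <- moments(c(-2, -1, 0, 1, 2))
  expect_equal(mo$skewness, 0)
  set.seed(6)
  x <- rnorm(1e5)
  mo2 <- moments(x)
  expect_lt(abs(mo2$skewness), 3 * sqrt(6 / 1e5))
  expect_lt(abs(mo2$kurtosis_excess), 3 * sqrt(24 / 1e5))
  expect_equal(mo2$kurtosis_raw, mo2$kurtosis_excess + 3)
  expect_error(moments(1:3), "n >= 4")
})

test_that("LMM with all sigmas zero reduces to the polynomial fit", {
  spec <- population_spec(n_groups = 2, n_methods = 2, n_tb_per_cell = 10,
                          sigma_tb = 0, sigma_method = 0, sigma_group = 0,
                          sigma_resid = 0.01, seed = 3)
  pop <- sample_population(spec)
  dec <- suppressWarnings(fit_lmm(pop$table))
  expect_true(all(dec$sigma2[c("tb", "method", "group")] < 0.05))
  # fixed coefficients recover the generator's mean curve
  expect_equal(dec$coefficients, spec$mean_curve$coefficients, tolerance = 0.05)
})

test_that("LMM recovers the generator's variance components", {
  spec <- population_spec(n_tb_per_cell = 30, seed = 41)
  pop <- sample_population(spec, design = sparse_crossed_design(100, 2))
  dec <- fit_lmm(pop$table)
  truth <- c(tb = 4.2, method = 3.4, group = 1.4, resid = 3.0)
  rel_err <- abs(dec$sd[names(truth)] - truth) / truth
  expect_true(all(rel_err < 0.25))
  expect_true(dec$converged)
  # refits are bitwise-reproducible
  dec2 <- fit_lmm(sample_population(spec, design = sparse_crossed_design(100, 2))$table)
  expect_identical(dec$sd, dec2$sd)
})

test_that("single-level random factors are dropped with variance zero", {
  pop <- sample_population(population_spec(
    n_groups = 1, n_methods = 1, n_tb_per_cell = 40, sigma_group = 0,
    sigma_method = 0, seed = 43))
  expect_warning(dec <- fit_lmm(pop$table), "single level")
  expect_equal(unname(dec$sigma2["group"]), 0)
  expect_equal(unname(dec$sigma2["method"]), 0)
  expect_gt(dec$sigma2[["tb"]], 1)
})

test_that("higher polynomial orders add almost no marginal R2", {
  pop <- sample_population(population_spec(
    n_groups = 4, n_methods = 1, n_tb_per_cell = 60, seed = 47))
  r2 <- vapply(3:5, function(k)
    suppressWarnings(fit_lmm(pop$table, poly_order = k))$r2_marginal,
    numeric(1))
  expect_lt(r2[2] - r2[1], 0.01)
  expect_lt(r2[3] - r2[1], 0.01)
})

test_that("Nakagawa-Schielzeth R2 follows the plug-in identities", {
  r2 <- r2_nakagawa(2, 1, 1)
  expect_equal(unname(r2), c(0.5, 0.75))
  expect_equal(unname(r2_nakagawa(3, 0, 0)), c(1, 1))
  expect_error(r2_nakagawa(0, 0, 0), "degenerate")
  # published SD line squares to the published variance line within rounding
  expect_equal(c(4.2, 3.4, 1.4)^2, c(17.6, 11.5, 1.98), tolerance = 0.02)
  # marginal <= conditional on fitted decompositions
  pop <- sample_population(population_spec(
    n_groups = 3, n_methods = 2, n_tb_per_cell = 8, seed = 51))
  dec <- fit_lmm(pop$table)
  expect_lte(dec$r2_marginal, dec$r2_conditional)
  expect_lte(dec$r2_conditional, 1)
})
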