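test_that("fences match hand-computed quartiles (type-7 convention)", {
  f <- compute_fences(values_table(1:5), k = 1.5)
  expect_equal(f$q1, 2)
  expect_equal(f$q3, 4)
  expect_equal(c(f$lower, f$upper), c(-1, 7))
  # all equal values: degenerate fences, nothing flagged
  fc <- compute_fences(values_table(rep(3, 6)), k = 1.75)
  expect_equal(c(fc$lower, fc$upper), c(3, 3))
  expect_false(any(flag_outliers(values_table(rep(3, 6)), fc)))
  # k = 0 collapses the fences to the quartiles
  f0 <- compute_fences(values_table(1:5), k = 1e-12)
  expect_equal(c(f0$lower, f0$upper), c(2, 4), tolerance = 1e-9)
  expect_error(compute_fences(values_table(1:3), k = 1.5), ">= 4 values")
})

test_that("flagging is strict: on-fence values are kept", {
  tb <- values_table(c(1, 2, 3, 4, 5, 7, 7.001))
  f <- compute_fences(values_table(1:5), k = 1.5)  # fences (-1, 7)
  fl <- flag_outliers(tb, f)
  expect_identical(fl, c(rep(FALSE, 6), TRUE))
  expect_error(flag_outliers(values_table(1, frequency_hz = 250), f), "no fences")
})

test_that("Gaussian flag rate at k = 1.5 is ~0.7%", {
  set.seed(2)
  tb <- values_table(rnorm(1e5))
  fl <- flag_outliers(tb, compute_fences(tb, k = 1.5))
  expect_lt(abs(mean(fl) - 0.007), 0.002)
})

test_that("flagged fraction is monotone non-increasing in k", {
  set.seed(3)
  tb <- values_table(rnorm(500))
  counts <- vapply(c(0.5, 1.0, 1.5, 1.75, 2.5),
                   function(k) sum(flag_outliers(tb, compute_fences(tb, k = k))),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("exclusion rules discard core-band outliers and truncate edges", {
  grid <- audiological_grid()
  mk <- function(id, y) data.frame(tb_id = id, group = "synthetic", method = "A",
                                   frequency_hz = grid, metf_db = y,
                                   unit = "displacement")
  base <- do.call(rbind, lapply(1:10, function(i) mk(sprintf("N%02d", i),
                                                     rep(0, 8) + (i - 5) / 10)))
  core_out <- mk("CORE", c(0, 0, 0, 0, 50, 0, 0, 0))        # outlier at 2 kHz
  edge_out <- mk("EDGE", c(50, 50, 0, 0, 0, 0, 0, 0))       # outliers at 125+250
  tb <- metf_table(rbind(base, core_out, edge_out))
  fences <- compute_fences(metf_table(base), k = 1.75)
  res <- apply_exclusion_rules(tb, flag_outliers(tb, fences))
  rep_ <- res$report
  expect_identical(rep_$verdict[rep_$tb_id == "CORE"], "discard")
  expect_identical(rep_$verdict[rep_$tb_id == "EDGE"], "truncate_low")
  expect_false("CORE" %in% res$table$tb_id)
  kept <- res$table$frequency_hz[res$table$tb_id == "EDGE"]
  expect_identical(sort(kept), grid[3:8])  # 500 Hz upward intact
  # untouched curves unchanged, report all-keep
  expect_true(all(rep_$verdict[grepl("^N", rep_$tb_id)] == "keep"))
  expect_equal(sum(res$table$tb_id %in% sprintf("N%02d", 1:10)), 80)
})

test_that("truncation removes everything outward of the innermost flag", {
  grid <- audiological_grid()
  mk <- function(id, y) data.frame(tb_id = id, group = "synthetic", method = "A",
                                   frequency_hz = grid, metf_db = y,
                                   unit = "displacement")
  base <- do.call(rbind, lapply(1:10, function(i) mk(sprintf("N%02d", i),
                                                     rep(0, 8) + (i - 5) / 10)))
  # flagged at 250 Hz only: 125 Hz is unflagged but outward -> removed too
  mid_out <- mk("MID", c(0, 50, 0, 0, 0, 0, 0, 0))
  both <- mk("BOTH", c(50, 0, 0, 0, 0, 0, 0, -50))
  tb <- metf_table(rbind(base, mid_out, both))
  fences <- compute_fences(metf_table(base), k = 1.75)
  res <- apply_exclusion_rules(tb, flag_outliers(tb, fences))
  expect_identical(sort(res$table$frequency_hz[res$table$tb_id == "MID"]),
                   grid[3:8])
  expect_identical(res$report$verdict[res$report$tb_id == "BOTH"], "truncate_both")
  expect_identical(sort(res$table$frequency_hz[res$table$tb_id == "BOTH"]),
                   grid[2:7])
})

test_that("verdicts are invariant to curve permutation and clean data passes", {
  tb <- make_flat_table(20, mu = -40, sd = 4, seed = 9)
  res1 <- screen_outliers(tb)
  shuffled <- as.data.frame(tb)[sample(nrow(tb)), ]
  res2 <- screen_outliers(metf_table(shuffled))
  v1 <- res1$report$verdict[order(res1$report$tb_id)]
  v2 <- res2$report$verdict[order(res2$report$tb_id)]
  expect_identical(v1, v2)
  # no flags -> identity, all-keep (identical curves: degenerate fences,
  # on-fence values are kept by the strict comparison)
  flat <- make_flat_table(8, mu = 0, sd = 0, seed = 10)
  res3 <- screen_outliers(flat)
  expect_equal(nrow(res3$table), nrow(flat))
  expect_true(all(res3$report$verdict == "keep"))
})

test_that("a clean synthetic population loses few curves to screening", {
  pop <- sample_population(population_spec(
    n_groups = 4, n_methods = 1, n_tb_per_cell = 50, seed = 31))
  res <- two_pass_screen(pop$table, k = 1.75)
  n_in <- length(unique(pop$table$tb_id))
  n_discarded <- sum(res$combined$report$verdict == "discard")
  expect_lt(n_discarded / n_in, 0.15)
})

test_that("two-pass screen catches pooled-only extremes in pass 2", {
  grid <- audiological_grid()
  mk <- function(id, grp, y) data.frame(tb_id = id, group = grp, method = "A",
                                        frequency_hz = grid, metf_db = y,
                                        unit = "displacement")
  # tight cell around 0, wide cell around 0; EXT is typical for the wide cell
  # but extreme for the pooled distribution
  tight <- do.call(rbind, lapply(1:30, function(i)
    mk(sprintf("T%02d", i), "G1", rep((i - 15) / 30, 8))))
  wide <- do.call(rbind, lapply(1:8, function(i)
    mk(sprintf("W%02d", i), "G2", rep((i - 4) * 8, 8))))
  ext <- mk("EXT", "G2", rep(34, 8))
  tb <- metf_table(rbind(tight, wide, ext))
  res <- two_pass_screen(tb, k = 1.75)
  expect_true("EXT" %in% res$by_cell$table$tb_id)       # survives its own cell
  expect_false("EXT" %in% res$combined$table$tb_id)     # pooled fences catch it
  # single subgroup: the two passes agree
  res1 <- two_pass_screen(metf_table(tight), k = 1.75)
  expect_identical(as.data.frame(res1$by_cell$table),
                   as.data.frame(res1$combined$table))
})
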