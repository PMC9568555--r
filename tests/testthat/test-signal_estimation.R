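hannover_tones <- c(125, 250, 500, 1000, 2000, 3000, 4000, 6000, 8000, 10000)

test_that("excitation frequencies must sit on exact FFT bins", {
  spec <- excitation_spec(hannover_tones, sample_rate_hz = 25600,
                          block_size = 1024, n_averages = 4)
  expect_identical(spec$bins, as.integer(hannover_tones / 25))  # 25 Hz bin width
  expect_error(excitation_spec(130, 25600, 1024), "exact FFT bin")
  expect_error(excitation_spec(1000, 25600, 1000), "power of two")
})

test_that("multisine has energy only at the excitation bins", {
  spec <- excitation_spec(250, sample_rate_hz = 25600, block_size = 1024,
                          n_averages = 1)
  x <- generate_multisine(spec, seed = 5)
  mag <- Mod(stats::fft(x))[1:513]
  peak <- mag[spec$bins + 1]
  expect_lt(max(mag[-(spec$bins + 1)]) / peak, 1e-10)

  # different seeds: same magnitude spectrum, different phases
  specm <- excitation_spec(c(125, 500, 2000), 25600, 1024, n_averages = 1)
  f1 <- stats::fft(generate_multisine(specm, seed = 1))
  f2 <- stats::fft(generate_multisine(specm, seed = 2))
  expect_equal(Mod(f1), Mod(f2), tolerance = 1e-8)
  expect_gt(max(Mod(Arg(f1[specm$bins + 1]) - Arg(f2[specm$bins + 1]))), 0.1)
})

test_that("averaged spectra satisfy gain and Cauchy-Schwarz identities", {
  spec <- excitation_spec(c(500, 1000), 25600, 1024, n_averages = 4)
  x <- generate_multisine(spec, seed = 1)
  pair <- structure(list(mic_v = x, ldv_v = 2 * x, sample_rate_hz = 25600),
                    class = "timeseries_pair")
  sp <- estimate_spectra(pair, 1024, 4)
  idx <- spec$bins + 1
  expect_equal(Mod(sp$sxy[idx]) / sp$sxx[idx], c(2, 2), tolerance = 1e-9)
  expect_error(estimate_spectra(pair, 1024, 100), "too short")

  # single average: |Sxy|^2 = Sxx*Syy exactly
  set.seed(2)
  pr <- structure(list(mic_v = rnorm(1024), ldv_v = rnorm(1024),
                       sample_rate_hz = 1024), class = "timeseries_pair")
  s1 <- estimate_spectra(pr, 1024, 1)
  expect_equal(Mod(s1$sxy)^2, s1$sxx * s1$syy, tolerance = 1e-8)

  # white-noise pair, 20 averages: Cauchy-Schwarz at all bins
  set.seed(3)
  pw <- structure(list(mic_v = rnorm(1024 * 20), ldv_v = rnorm(1024 * 20),
                       sample_rate_hz = 1024), class = "timeseries_pair")
  sw <- estimate_spectra(pw, 1024, 20)
  expect_true(all(Mod(sw$sxy)^2 <= sw$sxx * sw$syy * (1 + 1e-12)))
})

test_that("H1 transfer function recovers gains and applies calibration", {
  spec <- excitation_spec(c(500, 2000), 25600, 1024, n_averages = 2)
  pair <- simulate_metf_signals(c(6.0206, -6.0206), spec, snr_db = Inf, seed = 1)
  sp <- estimate_spectra(pair, 1024, 2)
  tf <- transfer_function(sp, spec$frequencies_hz)
  expect_equal(tf$magnitude, c(2, 0.5), tolerance = 1e-7)
  tf2 <- transfer_function(sp, spec$frequencies_hz, a_k = 2, b_k = 1)
  expect_equal(tf2$magnitude, 2 * tf$magnitude, tolerance = 1e-12)
  expect_error(transfer_function(sp, 333), "not an FFT bin")
})

test_that("coherence behaves like SNR/(1+SNR) and is scale-invariant", {
  spec <- excitation_spec(c(500, 1000, 2000), 25600, 1024, n_averages = 50)
  # identical channels: coherence 1 at excited bins
  x <- generate_multisine(spec, seed = 1)
  pr <- structure(list(mic_v = x, ldv_v = x, sample_rate_hz = 25600),
                  class = "timeseries_pair")
  sp <- estimate_spectra(pr, 1024, 50)
  expect_equal(coherence(sp)[spec$bins + 1], rep(1, 3), tolerance = 1e-9)
  expect_error(coherence(estimate_spectra(pr, 1024, 1)), ">= 2 averages")

  # independent channels: coherence -> 0 (below 0.2 at 50 averages)
  set.seed(4)
  pi_ <- structure(list(mic_v = rnorm(1024 * 50), ldv_v = rnorm(1024 * 50),
                        sample_rate_hz = 25600), class = "timeseries_pair")
  g2 <- coherence(estimate_spectra(pi_, 1024, 50))
  expect_lt(max(g2[spec$bins + 1]), 0.2)

  # output noise at 0 dB per-bin SNR: coherence ~ SNR/(1+SNR) = 0.5
  spec200 <- excitation_spec(c(500, 1000, 2000), 25600, 1024, n_averages = 200)
  pn <- simulate_metf_signals(c(0, 0, 0), spec200, snr_db = 0, seed = 6)
  spn <- estimate_spectra(pn, 1024, 200)
  g2n <- coherence(spn)[spec200$bins + 1]
  expect_true(all(abs(g2n - 0.5) < 0.1))

  # invariant to independent rescaling of either channel
  pr2 <- structure(list(mic_v = 3.7 * pn$mic_v, ldv_v = 0.2 * pn$ldv_v,
                        sample_rate_hz = 25600), class = "timeseries_pair")
  g2s <- coherence(estimate_spectra(pr2, 1024, 200))[spec200$bins + 1]
  expect_equal(g2s, g2n, tolerance = 1e-10)
})

test_that("adjacent-bin SNR matches hand values and simulation", {
  # peak 100 over flat neighbors of 1 -> 40 dB; peak equal to mean -> 0 dB
  mag <- rep(1, 101)
  mag[51] <- 100
  expect_equal(snr_adjacent_bins(mag, excited_bins = 50), 40)
  mag[51] <- 1
  expect_equal(snr_adjacent_bins(mag, excited_bins = 50), 0)

  # simulated multisine at a configured per-bin SNR of 20 dB: within +/- 3 dB
  spec <- excitation_spec(c(500, 1000, 2000), 25600, 1024, n_averages = 20)
  pr <- simulate_metf_signals(c(0, 0, 0), spec, snr_db = 20, seed = 8)
  sp <- estimate_spectra(pr, 1024, 20)
  snr <- snr_adjacent_bins(sqrt(sp$syy), spec$bins)
  expect_true(all(abs(snr - 20) < 3))
})

test_that("quality gates implement the three laboratory profiles", {
  est <- data.frame(frequency_hz = c(500, 2000), coherence = c(0.8, 0.9),
                    snr_db = c(15, 15))
  # coherence exactly 0.8 is invalid (strict inequality)
  expect_identical(quality_gate(est, "dresden"), c(FALSE, TRUE))
  expect_identical(quality_gate(est, "hannover"), c(TRUE, TRUE))
  # shanghai splits the threshold at 1 kHz: 15 dB passes below, fails at/above
  expect_identical(quality_gate(est, "shanghai"), c(TRUE, FALSE))
  est$snr_db <- c(30, 30)
  expect_identical(quality_gate(est, "shanghai"), c(TRUE, TRUE))
  expect_error(quality_gate(est, "oxford"))
  expect_error(quality_gate(data.frame(frequency_hz = 1, snr_db = 5), "dresden"),
               "coherence")
})

test_that("quality masks are monotone in simulation noise", {
  spec <- excitation_spec(audiological_grid(), 25600, 1024, n_averages = 10)
  gains <- packaged_reference("displacement")$mean_db
  prev_valid <- rep(TRUE, 8)
  for (snr in c(40, 25, 10, -5)) {
    est <- estimate_transfer(simulate_metf_signals(gains, spec, snr, seed = 21), spec)
    mask <- quality_gate(est, "hannover")
    expect_true(all(mask <= prev_valid | mask == prev_valid))
    # lowering SNR never turns an invalid frequency valid
    expect_true(all(!(mask & !prev_valid)))
    prev_valid <- mask
  }
})

test_that("signals CSV round-trips the pair", {
  spec <- excitation_spec(500, 25600, 256, n_averages = 2)
  pr <- simulate_metf_signals(0, spec, snr_db = 30, seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_signals_csv(pr, path)
  back <- read_signals_csv(path)
  expect_equal(back$mic_v, pr$mic_v, tolerance = 1e-6)
  expect_equal(back$sample_rate_hz, 25600, tolerance = 1e-3)
})
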