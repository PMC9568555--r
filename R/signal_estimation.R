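# Transfer-function estimation from two-channel voltage recordings.
#
# Excitation tones are constrained to exact FFT bins of the acquisition block,
# so rectangular (unwindowed) per-block FFTs are leakage-free and the bins
# between tones carry noise only - which is what makes the adjacent-bin SNR
# estimate meaningful.

#' Multisine excitation specification
#'
#' @param frequencies_hz Excitation tone frequencies; each must be an exact FFT
#'   bin, i.e. `f = m * sample_rate_hz / block_size` for integer `m >= 1`
#'   below Nyquist.
#' @param sample_rate_hz Sampling rate in Hz.
#' @param block_size FFT block length (power of two).
#' @param amplitude Per-tone amplitude (same for all tones).
#' @param n_averages Number of acquisition blocks to average (>= 1).
#' @return An `excitation_spec` list (with precomputed bin indices `bins`,
#'   1-based on the FFT of one block).
#' @export
#' @examples
#' excitation_spec(audiological_grid(), sample_rate_hz = 25600, block_size = 1024)
excitation_spec <- function(frequencies_hz, sample_rate_hz = 25600,
                            block_size = 1024, amplitude = 1, n_averages = 20) {
  validate_grid(frequencies_hz)
  stopifnot(sample_rate_hz > 0, block_size >= 2, n_averages >= 1, amplitude > 0)
  if (bitwAnd(as.integer(block_size), as.integer(block_size) - 1L) != 0L) {
    stop("block_size must be a power of two", call. = FALSE)
  }
  m <- frequencies_hz * block_size / sample_rate_hz
  if (any(abs(m - round(m)) > 1e-9)) {
    bad <- frequencies_hz[abs(m - round(m)) > 1e-9]
    stop(sprintf("excitation frequency not on an exact FFT bin: %s Hz",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  m <- as.integer(round(m))
  if (any(m < 1) || any(m >= block_size / 2)) {
    stop("excitation bins must lie strictly between DC and Nyquist", call. = FALSE)
  }
  structure(
    list(frequencies_hz = as.numeric(frequencies_hz), sample_rate_hz = sample_rate_hz,
         block_size = as.integer(block_size), amplitude = amplitude,
         n_averages = as.integer(n_averages), bins = m),
    class = "excitation_spec"
  )
}

#' Generate a periodic multisine excitation signal
#'
#' Sum of equal-amplitude sinusoids on the excitation bins with seeded random
#' phases. The signal is periodic with the block length, so it contains no
#' energy outside the excitation bins.
#'
#' @param spec An [excitation_spec()].
#' @param seed Integer seed for the phases.
#' @return Numeric vector of length `block_size * n_averages`.
#' @export
generate_multisine <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "excitation_spec"))
  phases <- local({
    set.seed(as.integer(seed))
    stats::runif(length(spec$bins), 0, 2 * pi)
  })
  synthesize_tones(spec, gains_linear = rep(1, length(spec$bins)), phases = phases)
}

# render sum of tones with per-tone linear gain; one block, then tiled
synthesize_tones <- function(spec, gains_linear, phases) {
  n <- spec$block_size
  t_idx <- 0:(n - 1)
  block <- rep(0, n)
  for (j in seq_along(spec$bins)) {
    block <- block + spec$amplitude * gains_linear[j] *
      cos(2 * pi * spec$bins[j] * t_idx / n + phases[j])
  }
  rep(block, spec$n_averages)
}

#' Simulate a two-channel METF measurement
#'
#' Renders a microphone channel (the multisine excitation) and a vibrometer
#' channel whose tone amplitudes are scaled by the target transfer magnitudes,
#' plus white Gaussian noise on the vibrometer channel calibrated so that the
#' weakest tone attains `snr_db` (per-bin signal-to-noise in the block FFT).
#' This is the ground-truth generator for end-to-end round-trip checks.
#'
#' @param gains_db Target transfer magnitudes in dB at `spec$frequencies_hz`.
#' @param spec An [excitation_spec()].
#' @param snr_db Per-bin SNR of the weakest tone (`Inf` = noiseless).
#' @param seed Integer seed (phases and noise).
#' @return A `timeseries_pair` list: `mic_v`, `ldv_v`, `sample_rate_hz`.
#' @export
simulate_metf_signals <- function(gains_db, spec, snr_db = Inf, seed = 1L) {
  stopifnot(inherits(spec, "excitation_spec"),
            length(gains_db) == length(spec$frequencies_hz))
  phases <- local({
    set.seed(as.integer(seed))
    stats::runif(length(spec$bins), 0, 2 * pi)
  })
  gains <- 10^(gains_db / 20)
  mic <- synthesize_tones(spec, rep(1, length(spec$bins)), phases)
  ldv <- synthesize_tones(spec, gains, phases)
  if (is.finite(snr_db)) {
    # per-bin tone power |A*N/2|^2 vs expected noise bin power sigma^2*N
    a_min <- spec$amplitude * min(gains)
    sigma2 <- a_min^2 * spec$block_size / (4 * 10^(snr_db / 10))
    noise <- local({
      set.seed(as.integer(seed) + 1L)
      stats::rnorm(length(ldv), sd = sqrt(sigma2))
    })
    ldv <- ldv + noise
  }
  structure(list(mic_v = mic, ldv_v = ldv, sample_rate_hz = spec$sample_rate_hz),
            class = "timeseries_pair")
}

#' Write / read a two-channel signals CSV (t_s, mic_v, ldv_v)
#'
#' @param pair A `timeseries_pair`.
#' @param path File path.
#' @return `path` (write) or a `timeseries_pair` (read).
#' @export
write_signals_csv <- function(pair, path) {
  stopifnot(inherits(pair, "timeseries_pair"))
  t_s <- (seq_along(pair$mic_v) - 1) / pair$sample_rate_hz
  utils::write.csv(data.frame(t_s = t_s, mic_v = pair$mic_v, ldv_v = pair$ldv_v),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_signals_csv
#' @export
read_signals_csv <- function(path) {
  d <- utils::read.csv(path)
  stopifnot(all(c("t_s", "mic_v", "ldv_v") %in% names(d)), nrow(d) >= 2)
  fs <- 1 / stats::median(diff(d$t_s))
  structure(list(mic_v = d$mic_v, ldv_v = d$ldv_v, sample_rate_hz = fs),
            class = "timeseries_pair")
}

#' Averaged auto- and cross-spectra
#'
#' Splits the pair into `n_averages` consecutive blocks, takes unwindowed FFTs
#' (excitation is bin-exact, so rectangular blocks are leakage-free) and
#' averages: `Sxx = mean |X|^2`, `Syy = mean |Y|^2`, `Sxy = mean conj(X)*Y`.
#' The Cauchy-Schwarz bound `|Sxy|^2 <= Sxx*Syy` holds at every bin.
#'
#' @param pair A `timeseries_pair` (mic = input x, LDV = output y).
#' @param block_size FFT block length.
#' @param n_averages Number of blocks to use; default all available.
#' @return A `spectral_estimate`: per-bin `frequency_hz`, `sxx`, `syy`
#'   (real), `sxy` (complex), plus `n_averages`, `block_size`,
#'   `sample_rate_hz`. Bins cover DC..Nyquist.
#' @export
estimate_spectra <- function(pair, block_size, n_averages = NULL) {
  stopifnot(inherits(pair, "timeseries_pair"))
  len <- length(pair$mic_v)
  stopifnot(length(pair$ldv_v) == len)
  if (is.null(n_averages)) n_averages <- len %/% block_size
  if (len < block_size * n_averages || n_averages < 1) {
    stop("signal too short for requested block_size * n_averages", call. = FALSE)
  }
  nb <- block_size %/% 2 + 1
  sxx <- syy <- numeric(nb)
  sxy <- complex(nb)
  for (b in seq_len(n_averages)) {
    idx <- ((b - 1) * block_size + 1):(b * block_size)
    X <- stats::fft(pair$mic_v[idx])[1:nb]
    Y <- stats::fft(pair$ldv_v[idx])[1:nb]
    sxx <- sxx + Mod(X)^2
    syy <- syy + Mod(Y)^2
    sxy <- sxy + Conj(X) * Y
  }
  structure(
    list(frequency_hz = (0:(nb - 1)) * pair$sample_rate_hz / block_size,
         sxx = sxx / n_averages, syy = syy / n_averages, sxy = sxy / n_averages,
         n_averages = as.integer(n_averages), block_size = as.integer(block_size),
         sample_rate_hz = pair$sample_rate_hz),
    class = "spectral_estimate"
  )
}

#' H1 transfer-function magnitude at the excited bins
#'
#' The H1 estimator `|Sxy| / Sxx`, scaled by calibration factors `a_k / b_k`
#' (output and input volts-to-physical-unit factors). H1 is the standard
#' choice when the excitation side is noise-free.
#'
#' @param spectra A `spectral_estimate`.
#' @param frequencies_hz Excited frequencies (must be exact bins of the
#'   estimate).
#' @param a_k,b_k Calibration factors for the output (LDV) and input (probe
#'   microphone) channels; scalars or per-frequency vectors. Default 1
#'   (volts treated as physical units, the simulation convention).
#' @return Data frame `frequency_hz`, `magnitude` (linear, >= 0).
#' @export
transfer_function <- function(spectra, frequencies_hz, a_k = 1, b_k = 1) {
  stopifnot(inherits(spectra, "spectral_estimate"))
  idx <- match_bins(spectra, frequencies_hz)
  if (any(spectra$sxx[idx] <= 0)) {
    stop("zero input power at an excited bin (degenerate input)", call. = FALSE)
  }
  a_k <- rep_len(a_k, length(idx))
  b_k <- rep_len(b_k, length(idx))
  data.frame(frequency_hz = frequencies_hz,
             magnitude = (a_k / b_k) * Mod(spectra$sxy[idx]) / spectra$sxx[idx])
}

match_bins <- function(spectra, frequencies_hz) {
  df <- spectra$sample_rate_hz / spectra$block_size
  m <- frequencies_hz / df
  if (any(abs(m - round(m)) > 1e-6)) {
    stop("requested frequency is not an FFT bin of this estimate", call. = FALSE)
  }
  as.integer(round(m)) + 1L  # 1-based, bin 0 = DC
}

#' Magnitude-squared coherence per bin
#'
#' `gamma^2 = |Sxy|^2 / (Sxx * Syy)`, in `[0, 1]`; `NaN` where a channel has
#' zero power. Requires at least 2 averages (a single average is identically
#' coherent).
#'
#' @param spectra A `spectral_estimate` with `n_averages >= 2`.
#' @return Numeric vector over all bins of the estimate.
#' @export
coherence <- function(spectra) {
  stopifnot(inherits(spectra, "spectral_estimate"))
  if (spectra$n_averages < 2) {
    stop("coherence needs >= 2 averages (identically 1 for a single average)",
         call. = FALSE)
  }
  denom <- spectra$sxx * spectra$syy
  g2 <- Mod(spectra$sxy)^2 / denom
  g2[denom == 0] <- NaN
  pmin(pmax(g2, 0), 1)
}

#' Adjacent-bin SNR at the excited bins
#'
#' Divides each excited bin's magnitude by the mean magnitude of its six
#' nearest non-excited neighbor bins (3 below / 3 above where possible); with
#' bin-exact multisine excitation those neighbors carry background noise only.
#' When a neighbor slot collides with another excited bin the next-nearest
#' non-excited bin is used (with a warning).
#'
#' @param magnitudes Per-bin magnitude spectrum (e.g. `sqrt(syy)`), bins
#'   DC..Nyquist.
#' @param excited_bins Integer bin numbers (0-based, DC = 0) of the excitation
#'   tones.
#' @param n_neighbors Number of noise bins per tone (default 6).
#' @return Numeric `snr_db` per excited bin: `20*log10(mag / mean(noise))`.
#' @export
snr_adjacent_bins <- function(magnitudes, excited_bins, n_neighbors = 6) {
  nb <- length(magnitudes)
  excited_idx <- as.integer(excited_bins) + 1L
  stopifnot(all(excited_idx >= 1), all(excited_idx <= nb))
  # exclude DC, Nyquist and all excited bins from the noise pool
  pool <- setdiff(2:(nb - 1), excited_idx)
  collided <- FALSE
  vapply(excited_idx, function(i) {
    d <- abs(pool - i)
    below <- pool[pool < i][order(abs(pool[pool < i] - i))]
    above <- pool[pool > i][order(abs(pool[pool > i] - i))]
    n_lo <- min(length(below), n_neighbors %/% 2)
    n_hi <- min(length(above), n_neighbors - n_lo)
    n_lo <- min(length(below), n_neighbors - n_hi)
    sel <- c(below[seq_len(n_lo)], above[seq_len(n_hi)])
    if (length(sel) < n_neighbors) {
      stop("not enough non-excited neighbor bins for SNR estimation", call. = FALSE)
    }
    # a gap wider than the slot count means an excited bin sat in the window
    if (!collided && max(abs(sel - i)) > n_neighbors %/% 2 + 1) {
      collided <<- TRUE
      warning("neighbor window collided with another excited bin; used next-nearest bins",
              call. = FALSE)
    }
    20 * log10(magnitudes[i] / mean(magnitudes[sel]))
  }, numeric(1))
}

#' Full transfer estimate with quality metrics
#'
#' Convenience wrapper: averaged spectra, calibrated H1 magnitude, coherence
#' and adjacent-bin SNR at the excitation frequencies.
#'
#' @param pair A `timeseries_pair`.
#' @param spec The [excitation_spec()] used to drive the measurement.
#' @param a_k,b_k Calibration factors (see [transfer_function()]).
#' @return A `transfer_estimate` data frame: `frequency_hz`, `magnitude`,
#'   `magnitude_db`, `coherence`, `snr_db`; attribute `n_averages`.
#' @export
estimate_transfer <- function(pair, spec, a_k = 1, b_k = 1) {
  stopifnot(inherits(spec, "excitation_spec"))
  sp <- estimate_spectra(pair, spec$block_size, spec$n_averages)
  tf <- transfer_function(sp, spec$frequencies_hz, a_k = a_k, b_k = b_k)
  g2 <- if (sp$n_averages >= 2) coherence(sp)[match_bins(sp, spec$frequencies_hz)]
        else rep(NA_real_, nrow(tf))
  snr <- snr_adjacent_bins(sqrt(sp$syy), spec$bins)
  out <- data.frame(frequency_hz = tf$frequency_hz, magnitude = tf$magnitude,
                    magnitude_db = 20 * log10(tf$magnitude),
                    coherence = g2, snr_db = snr)
  structure(out, class = c("transfer_estimate", "data.frame"),
            n_averages = sp$n_averages)
}

#' Laboratory quality gates
#'
#' Per-frequency validity mask under one of the three laboratory profiles:
#' `dresden` keeps points with coherence strictly greater than 0.8; `hannover`
#' keeps SNR > 12 dB; `shanghai` keeps SNR > 10 dB below 1 kHz and SNR > 20 dB
#' at and above 1 kHz (the boundary is assigned to the stricter rule).
#'
#' @param estimate A `transfer_estimate` (or data frame with the needed
#'   columns).
#' @param profile `"dresden"`, `"hannover"` or `"shanghai"`.
#' @return Logical mask aligned with the estimate's rows.
#' @export
quality_gate <- function(estimate, profile = c("dresden", "hannover", "shanghai")) {
  profile <- match.arg(profile)
  need <- if (profile == "dresden") "coherence" else "snr_db"
  if (is.null(estimate[[need]]) || all(is.na(estimate[[need]]))) {
    stop(sprintf("profile '%s' requires the '%s' field", profile, need),
         call. = FALSE)
  }
  switch(profile,
    dresden  = !is.na(estimate$coherence) & estimate$coherence > 0.8,
    hannover = !is.na(estimate$snr_db) & estimate$snr_db > 12,
    shanghai = !is.na(estimate$snr_db) &
      ifelse(estimate$frequency_hz < 1000, estimate$snr_db > 10, estimate$snr_db > 20)
  )
}
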