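# Shared fixture builders: small deterministic tables and populations.

# n curves on the audiological grid, i.i.d. Gaussian noise around mu
make_flat_table <- function(n, mu = 0, sd = 1, seed = 1, group = "synthetic",
                            method = "A", prefix = "T") {
  set.seed(seed)
  grid <- audiological_grid()
  metf_table(data.frame(
    tb_id = rep(sprintf("%s%03d", prefix, seq_len(n)), each = length(grid)),
    group = group, method = method,
    frequency_hz = rep(grid, times = n),
    metf_db = mu + stats::rnorm(n * length(grid), 0, sd),
    unit = "displacement", stringsAsFactors = FALSE
  ))
}

# single-frequency table from a plain vector of values
values_table <- function(values, frequency_hz = 1000) {
  metf_table(data.frame(
    tb_id = sprintf("V%06d", seq_along(values)), group = "synthetic",
    method = "A", frequency_hz = frequency_hz, metf_db = values,
    unit = "displacement", stringsAsFactors = FALSE
  ))
}

# sparse crossed design: n_levels group and method levels, each group paired
# with `per_group` consecutive method levels (connected, identifiable)
sparse_crossed_design <- function(n_levels = 100, per_group = 2) {
  g <- rep(seq_len(n_levels), each = per_group)
  m <- ((g - 1 + rep(seq_len(per_group) - 1, n_levels)) %% n_levels) + 1
  data.frame(group = sprintf("G%03d", g), method = sprintf("M%03d", m),
             stringsAsFactors = FALSE)
}

table2_stat_cols <- c("mean_db", "ci95_lo", "ci95_hi", "ti95_lo", "ti95_hi")
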