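# Shared fixture builders: small, deterministic cohorts.

small_config <- function(seed = 1L, ...) {
  sim_config(seed = seed, n_cells_per_group = 60, n_genes = 400,
             n_markers_per_class = 20, marker_log_fc = 1.5, ...)
}

two_class_cohort <- function(seed = 1L, marker_log_fc = 2, n = 80,
                             n_genes = 2000) {
  cfg <- sim_config(seed = seed, n_cells_per_group = n, n_genes = n_genes,
                    marker_log_fc = marker_log_fc)
  generate_query_cohort(cfg, classes = c("Dock5", "Lsp1"),
                        frac_low_quality = 0)
}

# Constructed sweep with explicit step metadata, for arithmetic tests.
make_sweep <- function(voltage, fs = 10000, onset_s = 0.1, duration_s = 0.5,
                       amplitude_pA = -40) {
  t <- seq(0, length.out = length(voltage), by = 1 / fs)
  cur <- numeric(length(voltage))
  cur[t >= onset_s & t < onset_s + duration_s] <- amplitude_pA
  out <- tibble::tibble(time_s = t, voltage_mV = voltage, current_pA = cur)
  attr(out, "onset_s") <- onset_s
  attr(out, "duration_s") <- duration_s
  attr(out, "amplitude_pA") <- amplitude_pA
  attr(out, "fs_hz") <- fs
  out
}
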