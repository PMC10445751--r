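# Synthetic patch-seq generator: paired expression and current-clamp traces
# from a single-compartment RC membrane model with an additive
# hyperpolarization-activated sag term and a thresholded spike generator
# (stereotyped spike waveforms with configurable AHP).

#' Current-injection protocol
#'
#' The default protocol holds the four required steps: a -40 pA pulse
#' (120 ms) for input resistance and membrane time constant, a -200 pA pulse
#' (500 ms) for the sag ratio, a rheobase ramp of 500 ms depolarizing sweeps
#' from +5 pA to +300 pA, and a +300 pA / 1000 ms suprathreshold step for
#' spike frequency.
#'
#' @param ramp_increment_pA Step size of the rheobase ramp (default 5 pA).
#' @param fs_hz Sampling rate (default 10 kHz).
#' @return Tibble with one row per sweep: `kind`, `amplitude_pA`, `onset_s`,
#'   `duration_s`, `total_s`, `fs_hz`.
#' @export
default_protocol <- function(ramp_increment_pA = 5, fs_hz = 10000) {
  ramp_amps <- seq(5, 300, by = ramp_increment_pA)
  dplyr::bind_rows(
    tibble(kind = "hyperpol_40", amplitude_pA = -40, onset_s = 0.1,
           duration_s = 0.12, total_s = 0.32),
    tibble(kind = "hyperpol_200", amplitude_pA = -200, onset_s = 0.1,
           duration_s = 0.5, total_s = 0.7),
    tibble(kind = "rheobase_ramp", amplitude_pA = ramp_amps, onset_s = 0.1,
           duration_s = 0.5, total_s = 0.7),
    tibble(kind = "suprathreshold_300", amplitude_pA = 300, onset_s = 0.1,
           duration_s = 1.0, total_s = 1.2)
  ) %>% mutate(fs_hz = fs_hz)
}

required_protocol_kinds <- c("hyperpol_40", "hyperpol_200", "rheobase_ramp",
                             "suprathreshold_300")

validate_protocol <- function(protocol) {
  missing <- setdiff(required_protocol_kinds, unique(protocol$kind))
  if (length(missing)) {
    abort(paste0("Protocol is missing required step(s): ",
                 paste(missing, collapse = ", ")))
  }
  invisible(protocol)
}

#' Electrophysiological class presets
#'
#' Per-subtype means and standard deviations of the membrane-model
#' parameters. The AHP, spike-latency and STDB presets follow the reported
#' subtype statistics for fast-spiking Dock5+ NGCs (shallow AHP, short
#' latency, prominent subthreshold depolarizing bump) versus late-spiking
#' Lsp1+ NGCs (AHP -14.6 +/- 1 vs -23.4 +/- 0.9 mV; latency 50.3 +/- 5.4 vs
#' 205.3 +/- 25.4 ms; STDB 3.2 +/- 0.4 vs 0.8 +/- 0.4 mV).
#'
#' @return Tibble with one row per (class, parameter): `class`, `param`,
#'   `mean`, `sd`.
#' @export
ephys_presets <- function() {
  dplyr::bind_rows(
    tibble(class = "Dock5",
           param = c("rmp_mV", "rin_MOhm", "tau_ms", "sag_frac", "latency_ms",
                     "ahp_mV", "stdb_mV", "freq_hz", "rheobase_pA"),
           mean = c(-65, 150, 15, 0.10, 50.3, -14.6, 3.2, 40, 100),
           sd = c(2, 15, 2, 0.02, 5.4, 1.0, 0.4, 5, 10)),
    tibble(class = "Lsp1",
           param = c("rmp_mV", "rin_MOhm", "tau_ms", "sag_frac", "latency_ms",
                     "ahp_mV", "stdb_mV", "freq_hz", "rheobase_pA"),
           mean = c(-65, 200, 20, 0.15, 205.3, -23.4, 0.8, 25, 80),
           sd = c(2, 20, 2, 0.02, 25.4, 0.9, 0.4, 4, 10))
  )
}

# Stereotyped spike waveform, sampled at `fs`. Offsets are relative to the
# voltage at the 20 mV/ms upstroke crossing (index `crossing_idx`), so the
# planted threshold and AHP are expressed in the same reference frame the
# feature extractor uses. Returned trough equals `ahp_mV` exactly.
spike_waveform <- function(ahp_mV, fs = 10000, amp_mV = 70) {
  dt_ms <- 1000 / fs
  # upstroke rates (mV/ms): slow foot, then fast rise; 20 mV/ms is crossed at
  # the step from 10 to 30.
  up_rates <- c(2, 5, 10, 30, 80, 140, 140, 140)
  v <- cumsum(up_rates * dt_ms)
  v <- v - v[3]     # sample 3 is the 20 mV/ms forward-difference crossing
  peak_reached <- max(v)
  if (peak_reached < amp_mV) {
    v <- c(v, seq(peak_reached + 14, amp_mV, by = 14))
  }
  down <- seq(max(v), ahp_mV, by = -10 * dt_ms * 10)  # -100 mV/ms fall
  recover <- ahp_mV * exp(-seq(dt_ms, 8, by = dt_ms) / 3)
  w <- c(v, down[-1], ahp_mV, recover)
  list(w = w, crossing_idx = 3L, foot = v[1])
}

# Membrane response of one sweep; returns a voltage vector.
synth_sweep <- function(kind, amplitude_pA, onset_s, duration_s, total_s,
                        fs, par, noise_sd) {
  t <- seq(0, total_s - 1 / fs, by = 1 / fs)
  v <- rep(par$rmp_mV, length(t))
  on <- t >= onset_s & t < onset_s + duration_s
  ts <- t[on] - onset_s
  tau_s <- par$tau_ms / 1000
  dv_inf <- amplitude_pA * par$rin_MOhm / 1000   # pA * MOhm = uV; /1000 -> mV
  spiking <- kind %in% c("rheobase_ramp", "suprathreshold_300") &&
    amplitude_pA >= par$rheobase_pA
  if (kind == "hyperpol_200") {
    # RC charge with sag relaxation that engages after the peak (8 tau)
    charge <- dv_inf * (1 - exp(-ts / tau_s))
    t_peak <- 8 * tau_s
    relax <- 1 - par$sag_frac * (1 - exp(-pmax(ts - t_peak, 0) / 0.05))
    v[on] <- par$rmp_mV + charge * relax
  } else if (!spiking) {
    # passive RC response, capped below spike threshold for depolarizing steps
    target <- dv_inf
    if (amplitude_pA > 0) {
      target <- min(dv_inf, par$ap_threshold_mV - spike_foot_offset(fs) -
                      par$rmp_mV - 1)
    }
    v[on] <- par$rmp_mV + target * (1 - exp(-ts / tau_s))
    if (kind == "rheobase_ramp" && amplitude_pA == par$last_sub_amp) {
      # subthreshold depolarizing bump mid-step
      v[on] <- v[on] + par$stdb_mV * exp(-((ts - duration_s / 2)^2) / (2 * 0.02^2))
    }
  } else {
    # depolarize to just below threshold fast enough to settle before the
    # first spike, but keeping the rise well under the 20 mV/ms detector
    sub_level <- par$ap_threshold_mV + spike_foot_offset(fs)
    wf <- spike_waveform(par$ahp_mV, fs)
    lat0_s <- if (kind == "suprathreshold_300") {
      par$latency_ms / 1000 * par$rheobase_pA / amplitude_pA
    } else par$latency_ms / 1000
    rise_s <- max(lat0_s / 8, (sub_level - par$rmp_mV) / 15 / 1000)
    v[on] <- par$rmp_mV + (sub_level - par$rmp_mV) * (1 - exp(-ts / rise_s))
    lat_s <- lat0_s
    n_spikes <- if (kind == "suprathreshold_300") {
      max(1L, round(par$freq_hz * duration_s))
    } else par$n_rheo_spikes
    period <- if (n_spikes > 1) (duration_s - lat_s - 0.02) / (n_spikes - 1) else 0
    spike_times <- lat_s + period * (seq_len(n_spikes) - 1)
    on_idx <- which(on)
    for (st in spike_times) {
      # place so the 20 mV/ms crossing lands exactly at onset + st
      i0 <- round((onset_s + st) * fs) + 1L - (wf$crossing_idx - 1L)
      idx <- i0:(i0 + length(wf$w) - 1L)
      ok <- idx >= min(on_idx) & idx <= length(v)
      v[idx[ok]] <- par$ap_threshold_mV + wf$w[ok]
    }
  }
  if (noise_sd > 0) v <- v + rnorm(length(v), 0, noise_sd)
  v
}

# Relative voltage of the spike-waveform foot below the threshold crossing.
spike_foot_offset <- function(fs) spike_waveform(-15, fs)$foot

#' Generate a synthetic patch-seq cohort
#'
#' Each cell receives (i) expression counts from its class's marker model and
#' (ii) a full set of current-clamp sweeps synthesized from a
#' single-compartment membrane model whose parameters are drawn from the
#' class presets and modulated linearly by cortical depth. True parameters
#' are recorded per cell.
#'
#' Depth dependence: spike latency increases with depth for both subtypes
#' and the sag fraction increases slightly with depth; slopes are stated per
#' unit depth (0-1 normalized across the sampled range).
#'
#' @param config A [sim_config()].
#' @param protocol A protocol tibble (see [default_protocol()]); must contain
#'   the four required step kinds.
#' @param classes Subtype labels with presets (default Dock5/Lsp1).
#' @param n_per_class Cells per class (default 20 and 27, recycled).
#' @param presets Preset tibble as from [ephys_presets()].
#' @param noise_sd_mV Additive Gaussian voltage noise (default 0.2 mV); 0
#'   gives noise-free traces.
#' @param depth_latency_slope Added ms of latency per normalized depth unit.
#' @return List with `expr` (an `ngc_counts`), `traces` (tibble: one row per
#'   sweep with a `voltage` list-column), and `truth` (per-cell tibble of
#'   planted parameters and depth).
#' @export
generate_patchseq_cells <- function(config, protocol = default_protocol(),
                                    classes = c("Dock5", "Lsp1"),
                                    n_per_class = c(20L, 27L),
                                    presets = ephys_presets(),
                                    noise_sd_mV = 0.2,
                                    depth_latency_slope = 30) {
  validate_protocol(protocol)
  n_per_class <- rep_len(n_per_class, length(classes))
  n_cells <- sum(n_per_class)
  cell_class <- rep(classes, times = n_per_class)
  model <- base_gene_model(config, classes)
  fs <- protocol$fs_hz[1]
  ramp_amps <- sort(protocol$amplitude_pA[protocol$kind == "rheobase_ramp"])
  inc <- if (length(ramp_amps) > 1) diff(ramp_amps)[1] else 5
  with_seed(substream_seed(config$seed, "patchseq"), {
    # expression
    log_rel <- vapply(cell_class, function(cl) class_profile(model, config, cl),
                      numeric(config$n_genes))
    colnames(log_rel) <- sprintf("ps_%03d", seq_len(n_cells))
    rownames(log_rel) <- model$ids
    counts <- sample_counts(log_rel, config)
    depth <- runif(n_cells, 0, 600)    # um from pia
    d01 <- depth / 600
    # per-cell membrane parameters
    truth <- purrr::map(seq_len(n_cells), function(i) {
      pr <- presets[presets$class == cell_class[i], ]
      par <- setNames(rnorm(nrow(pr), pr$mean, pr$sd), pr$param)
      par["latency_ms"] <- max(5, par["latency_ms"] + depth_latency_slope * (d01[i] - 0.5))
      par["sag_frac"] <- min(0.4, max(0, par["sag_frac"] + 0.04 * (d01[i] - 0.5)))
      par["stdb_mV"] <- max(0, par["stdb_mV"])
      par["rin_MOhm"] <- max(50, par["rin_MOhm"])
      par["freq_hz"] <- max(5, round(par["freq_hz"]))
      # snap rheobase to the ramp grid so the first spiking sweep is exact
      par["rheobase_pA"] <- ramp_amps[which.min(abs(ramp_amps - par["rheobase_pA"]))]
      as.list(par)
    })
    traces <- purrr::map(seq_len(n_cells), function(i) {
      par <- truth[[i]]
      par$ap_threshold_mV <- -40
      par$n_rheo_spikes <- 2L
      par$last_sub_amp <- par$rheobase_pA - inc
      sweeps <- protocol %>%
        mutate(cell_id = sprintf("ps_%03d", i),
               sweep_id = sprintf("%s_swp%02d", cell_id, row_number()))
      sweeps$voltage <- purrr::pmap(
        list(sweeps$kind, sweeps$amplitude_pA, sweeps$onset_s,
             sweeps$duration_s, sweeps$total_s),
        function(kind, amp, onset, dur, total) {
          synth_sweep(kind, amp, onset, dur, total, fs, par, noise_sd_mV)
        })
      sweeps
    }) %>% dplyr::bind_rows()
    truth_tbl <- tibble(cell_id = sprintf("ps_%03d", seq_len(n_cells)),
                        true_class = cell_class,
                        true_depth = depth) %>%
      dplyr::bind_cols(dplyr::bind_rows(purrr::map(truth, as_tibble)))
    cells <- tibble(cell_id = colnames(counts),
                    true_class = cell_class,
                    platform = "patchseq",
                    tdtom = TRUE, gfp = TRUE,
                    n_genes = full_scale_genes(counts, config$n_genes),
                    n_umis = full_depth_umis(n_cells),
                    n_reads = full_depth_umis(n_cells) * 3L,
                    mito_fraction = stats::rbeta(n_cells, 2, 38),
                    exonic_fraction = stats::rbeta(n_cells, 30, 10))
    list(expr = ngc_counts(counts, cells, model$genes),
         traces = traces, truth = truth_tbl)
  })
}

#' Expand a stored sweep into a long trace tibble
#'
#' @param traces Trace tibble from [generate_patchseq_cells()].
#' @param cell_id,kind,amplitude_pA Selectors; the first matching sweep is
#'   returned.
#' @return Tibble `time_s`, `voltage_mV`, `current_pA` with step metadata
#'   attached as attributes (`onset_s`, `duration_s`, `amplitude_pA`,
#'   `fs_hz`).
#' @export
get_sweep <- function(traces, cell_id, kind = NULL, amplitude_pA = NULL) {
  sel <- traces$cell_id == cell_id
  if (!is.null(kind)) sel <- sel & traces$kind == kind
  if (!is.null(amplitude_pA)) sel <- sel & traces$amplitude_pA == amplitude_pA
  if (!any(sel)) abort("No sweep matches the requested step.")
  row <- traces[which(sel)[1], ]
  v <- row$voltage[[1]]
  fs <- row$fs_hz
  t <- seq(0, length.out = length(v), by = 1 / fs)
  cur <- numeric(length(v))
  cur[t >= row$onset_s & t < row$onset_s + row$duration_s] <- row$amplitude_pA
  out <- tibble(time_s = t, voltage_mV = v, current_pA = cur)
  attr(out, "onset_s") <- row$onset_s
  attr(out, "duration_s") <- row$duration_s
  attr(out, "amplitude_pA") <- row$amplitude_pA
  attr(out, "fs_hz") <- fs
  out
}

#' Write traces as one CSV per cell
#'
#' Columns `time_s`, `voltage_mV`, `current_pA`, `sweep_id` at the protocol
#' sampling rate.
#'
#' @param traces Trace tibble from [generate_patchseq_cells()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_traces_csv <- function(traces, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (cid in unique(traces$cell_id)) {
    rows <- traces[traces$cell_id == cid, ]
    long <- purrr::map(seq_len(nrow(rows)), function(i) {
      s <- get_sweep(rows, cid, kind = rows$kind[i],
                     amplitude_pA = rows$amplitude_pA[i])
      s$sweep_id <- rows$sweep_id[i]
      s
    }) %>% dplyr::bind_rows()
    readr::write_csv(long, file.path(dir, paste0(cid, ".csv")))
  }
  invisible(dir)
}
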