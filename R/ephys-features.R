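# Current-clamp feature extraction. All operational windows are documented
# artifact choices: steady state = mean over the last 20% of the step,
# baseline = mean before onset, sag V_end = mean of the last 5 ms of the
# step, AHP window = 50 ms after the spike.

trace_attr <- function(trace, name, override) {
  if (!is.null(override)) return(override)
  a <- attr(trace, name)
  if (is.null(a)) abort(sprintf("Trace attribute '%s' missing; pass it explicitly.", name))
  a
}

step_windows <- function(trace, onset_s, duration_s) {
  t <- trace$time_s
  list(baseline = t < onset_s,
       on = t >= onset_s & t < onset_s + duration_s,
       steady = t >= onset_s + 0.8 * duration_s & t < onset_s + duration_s,
       last5ms = t >= onset_s + duration_s - 0.005 & t < onset_s + duration_s)
}

#' Input resistance from a -40 pA step
#'
#' Ohm's law on the steady-state deflection: R = dV/dI with dV the mean over
#' the last 20% of the step minus the pre-onset baseline mean. Units MOhm
#' (mV / pA x 1000).
#'
#' @param trace Sweep tibble (`time_s`, `voltage_mV`, `current_pA`), e.g.
#'   from [get_sweep()]; step metadata read from attributes unless given.
#' @param onset_s,duration_s,amplitude_pA Step definition overrides.
#' @return Input resistance in MOhm; warns when implausibly small.
#' @export
input_resistance <- function(trace, onset_s = NULL, duration_s = NULL,
                             amplitude_pA = NULL) {
  onset_s <- trace_attr(trace, "onset_s", onset_s)
  duration_s <- trace_attr(trace, "duration_s", duration_s)
  amplitude_pA <- trace_attr(trace, "amplitude_pA", amplitude_pA)
  if (amplitude_pA == 0) abort("Step amplitude is zero; no step present.")
  w <- step_windows(trace, onset_s, duration_s)
  if (!any(w$baseline) || !any(w$steady)) abort("Step/baseline windows empty.")
  dv <- mean(trace$voltage_mV[w$steady]) - mean(trace$voltage_mV[w$baseline])
  r <- dv / amplitude_pA * 1000
  if (r <= 0) warn(sprintf("Implausible input resistance (%.1f MOhm).", r))
  r
}

#' Membrane time constant from a -40 pA step
#'
#' Least-squares monoexponential fit V(t) = Vinf + A exp(-t/tau) on the
#' first 100 ms after step onset.
#'
#' @inheritParams input_resistance
#' @param fit_window_s Fit window after onset (default 0.1 s).
#' @return Tau in ms (`NA` with a warning on non-convergence); attribute
#'   `r_squared` carries the fit quality, with a warning below 0.8.
#' @export
membrane_tau <- function(trace, onset_s = NULL, duration_s = NULL,
                         fit_window_s = 0.1) {
  onset_s <- trace_attr(trace, "onset_s", onset_s)
  sel <- trace$time_s >= onset_s & trace$time_s < onset_s + fit_window_s
  if (sum(sel) < 10) abort("Need at least 100 ms of post-onset samples.")
  tt <- (trace$time_s[sel] - onset_s) * 1000  # ms
  vv <- trace$voltage_mV[sel]
  v_inf0 <- mean(tail(vv, max(5, round(length(vv) * 0.1))))
  a0 <- vv[1] - v_inf0
  fit <- tryCatch(
    minpack.lm::nlsLM(vv ~ v_inf + a * exp(-tt / tau),
                      start = list(v_inf = v_inf0, a = a0, tau = 15),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    warn("Monoexponential fit did not converge; tau is NA.")
    return(NA_real_)
  }
  r2 <- 1 - sum(residuals(fit)^2) / sum((vv - mean(vv))^2)
  if (is.finite(r2) && r2 < 0.8) {
    warn(sprintf("Poor monoexponential fit (R^2 = %.2f).", r2))
  }
  tau <- unname(coef(fit)["tau"])
  attr(tau, "r_squared") <- r2
  tau
}

#' Sag ratio from a -200 pA step
#'
#' (V_min - V_end) / V_min with V_min the extreme voltage during the
#' hyperpolarizing step and V_end the mean of its last 5 ms. By default both
#' are baseline-subtracted deflections, making the ratio positive for
#' sagging cells and zero without sag; `mode = "absolute"` uses raw
#' voltages.
#'
#' V_min is taken on a lightly smoothed trace (moving average over
#' `smooth_ms`), the single-sweep analogue of measuring on averaged repeat
#' sweeps: a raw minimum over thousands of noisy samples is biased by the
#' noise extreme.
#'
#' @inheritParams input_resistance
#' @param mode `"deflection"` (default) or `"absolute"`.
#' @param smooth_ms Moving-average window for locating V_min (default 5 ms;
#'   0 disables smoothing).
#' @return Sag ratio (dimensionless).
#' @export
sag_ratio <- function(trace, onset_s = NULL, duration_s = NULL,
                      mode = c("deflection", "absolute"), smooth_ms = 5) {
  mode <- match.arg(mode)
  onset_s <- trace_attr(trace, "onset_s", onset_s)
  duration_s <- trace_attr(trace, "duration_s", duration_s)
  w <- step_windows(trace, onset_s, duration_s)
  if (!any(w$on)) abort("Step window empty; step absent.")
  v <- trace$voltage_mV
  if (smooth_ms > 0) {
    fs <- attr(trace, "fs_hz") %||%
      round(1 / median(diff(trace$time_s)))
    k <- max(1L, round(smooth_ms / 1000 * fs))
    sm <- as.numeric(stats::filter(v, rep(1 / k, k), sides = 2))
    v <- ifelse(is.na(sm), v, sm)
  }
  base <- mean(trace$voltage_mV[w$baseline])
  v_min <- min(v[w$on])
  v_end <- mean(trace$voltage_mV[w$last5ms])
  if (mode == "deflection") {
    v_min <- v_min - base
    v_end <- v_end - base
  }
  if (abs(v_min) < 1e-9) return(0)
  (v_min - v_end) / v_min
}

#' Detect action potentials by dV/dt threshold
#'
#' Spikes are flagged where the forward-difference dV/dt first exceeds
#' `dvdt_threshold`; crossings within `merge_ms` of the previous spike are
#' merged. The threshold voltage is the voltage at the crossing sample.
#'
#' @param voltage Numeric voltage vector (mV), or a sweep tibble.
#' @param fs_hz Sampling rate (read from the tibble attribute when omitted).
#' @param dvdt_threshold Upstroke threshold in mV/ms (default 20).
#' @param merge_ms Refractory merge window (default 2 ms).
#' @return Tibble (`index`, `time_s`, `threshold_mV`, `peak_mV`,
#'   `peak_index`); zero rows when no spike.
#' @export
detect_spikes <- function(voltage, fs_hz = NULL, dvdt_threshold = 20,
                          merge_ms = 2) {
  if (is.data.frame(voltage)) {
    fs_hz <- fs_hz %||% attr(voltage, "fs_hz")
    voltage <- voltage$voltage_mV
  }
  if (is.null(fs_hz)) abort("`fs_hz` required.")
  dvdt <- diff(voltage) * fs_hz / 1000  # mV per ms
  hits <- which(dvdt >= dvdt_threshold)
  if (length(hits) == 0) {
    return(tibble(index = integer(), time_s = double(),
                  threshold_mV = double(), peak_mV = double(),
                  peak_index = integer()))
  }
  min_gap <- merge_ms / 1000 * fs_hz
  starts <- hits[c(TRUE, diff(hits) > min_gap)]
  peak_info <- purrr::map(starts, function(i) {
    win <- i:min(length(voltage), i + round(0.005 * fs_hz))
    pk <- win[which.max(voltage[win])]
    list(peak = voltage[pk], pk_idx = pk)
  })
  tibble(index = starts,
         time_s = (starts - 1) / fs_hz,
         threshold_mV = voltage[starts],
         peak_mV = map_dbl(peak_info, "peak"),
         peak_index = as.integer(map_dbl(peak_info, "pk_idx")))
}

#' Single-AP and subthreshold features from a rheobase ramp
#'
#' Scans depolarizing sweeps in increasing amplitude order; the first sweep
#' with at least one spike defines rheobase, and its first action potential
#' provides the single-AP parameters. Latency is the time from step onset to
#' the first threshold crossing; AHP is the minimum voltage within 50 ms
#' after the spike minus the threshold voltage (negative); the STDB is
#' computed on the last fully subthreshold sweep as max(V) during the step
#' minus the steady-state mean.
#'
#' @param sweeps Trace tibble rows of one cell's `rheobase_ramp` (as stored
#'   by [generate_patchseq_cells()]), any order.
#' @param dvdt_threshold,merge_ms Spike-detection parameters.
#' @return Tibble row: `rheobase_pA`, `spike_latency_ms`, `ap_threshold_mV`,
#'   `ap_amplitude_mV`, `ahp_mV`, `stdb_mV`. Spike features are `NA` when no
#'   sweep spikes.
#' @export
first_ap_features <- function(sweeps, dvdt_threshold = 20, merge_ms = 2) {
  sweeps <- sweeps[order(sweeps$amplitude_pA), ]
  fs <- sweeps$fs_hz[1]
  spike_tbls <- purrr::map(seq_len(nrow(sweeps)), function(i) {
    detect_spikes(sweeps$voltage[[i]], fs, dvdt_threshold, merge_ms)
  })
  n_spk <- vapply(spike_tbls, nrow, integer(1))
  first_idx <- which(n_spk > 0)[1]
  out <- tibble(rheobase_pA = NA_real_, spike_latency_ms = NA_real_,
                ap_threshold_mV = NA_real_, ap_amplitude_mV = NA_real_,
                ahp_mV = NA_real_, stdb_mV = NA_real_)
  if (is.na(first_idx)) return(out)
  row <- sweeps[first_idx, ]
  spk <- spike_tbls[[first_idx]][1, ]
  v <- row$voltage[[1]]
  out$rheobase_pA <- row$amplitude_pA
  out$spike_latency_ms <- (spk$time_s - row$onset_s) * 1000
  out$ap_threshold_mV <- spk$threshold_mV
  out$ap_amplitude_mV <- spk$peak_mV - spk$threshold_mV
  ahp_win <- spk$peak_index:min(length(v), spk$index + round(0.05 * fs))
  out$ahp_mV <- min(v[ahp_win]) - spk$threshold_mV
  sub_idx <- first_idx - 1
  if (sub_idx >= 1) {
    sub <- sweeps[sub_idx, ]
    vs <- sub$voltage[[1]]
    t <- seq(0, length.out = length(vs), by = 1 / fs)
    on <- t >= sub$onset_s & t < sub$onset_s + sub$duration_s
    steady <- t >= sub$onset_s + 0.8 * sub$duration_s &
      t < sub$onset_s + sub$duration_s
    out$stdb_mV <- max(vs[on]) - mean(vs[steady])
  }
  out
}

#' Spike frequency from a suprathreshold step
#'
#' Spike count during the step divided by the step duration, so both 500 ms
#' and 1000 ms protocol variants are handled.
#'
#' @inheritParams input_resistance
#' @param dvdt_threshold,merge_ms Spike-detection parameters.
#' @return Frequency in Hz.
#' @export
spike_frequency <- function(trace, onset_s = NULL, duration_s = NULL,
                            dvdt_threshold = 20, merge_ms = 2) {
  onset_s <- trace_attr(trace, "onset_s", onset_s)
  duration_s <- trace_attr(trace, "duration_s", duration_s)
  spk <- detect_spikes(trace, dvdt_threshold = dvdt_threshold,
                       merge_ms = merge_ms)
  n <- sum(spk$time_s >= onset_s & spk$time_s < onset_s + duration_s)
  n / duration_s
}

#' Extract the full feature table from a trace set
#'
#' Runs every extractor per cell: input resistance and membrane time
#' constant from the -40 pA step, sag ratio from the -200 pA step, single-AP
#' and STDB features from the rheobase ramp, spike frequency from the
#' +300 pA step, and resting membrane potential from the -40 pA baseline.
#'
#' @param traces Trace tibble from [generate_patchseq_cells()] (or built to
#'   the same shape).
#' @param sag_mode Passed to [sag_ratio()].
#' @return Tibble, one row per cell, columns `cell_id`, `rmp_mV`,
#'   `rin_MOhm`, `tau_ms`, `sag_ratio`, `rheobase_pA`, `spike_latency_ms`,
#'   `ap_threshold_mV`, `ap_amplitude_mV`, `ahp_mV`, `stdb_mV`,
#'   `spike_freq_Hz`.
#' @export
extract_ephys_features <- function(traces, sag_mode = "deflection") {
  purrr::map(unique(traces$cell_id), function(cid) {
    s40 <- get_sweep(traces, cid, kind = "hyperpol_40")
    s200 <- get_sweep(traces, cid, kind = "hyperpol_200")
    s300 <- get_sweep(traces, cid, kind = "suprathreshold_300")
    ramp <- traces[traces$cell_id == cid & traces$kind == "rheobase_ramp", ]
    ap <- first_ap_features(ramp)
    tau <- suppressWarnings(membrane_tau(s40))
    tibble(cell_id = cid,
           rmp_mV = mean(s40$voltage_mV[s40$time_s < attr(s40, "onset_s")]),
           rin_MOhm = suppressWarnings(input_resistance(s40)),
           tau_ms = as.numeric(tau),
           sag_ratio = sag_ratio(s200, mode = sag_mode)) %>%
      dplyr::bind_cols(ap) %>%
      mutate(spike_freq_Hz = spike_frequency(s300))
  }) %>% dplyr::bind_rows()
}
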