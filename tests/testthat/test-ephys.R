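# Feature extraction arithmetic, spike detection, subtype assignment and
# feature-level statistics.

test_that("input resistance is Ohm's law on the steady-state deflection", {
  fs <- 10000
  n <- 0.4 * fs
  v <- rep(-65, n)
  t <- seq(0, length.out = n, by = 1 / fs)
  v[t >= 0.1 & t < 0.22] <- -69            # -4 mV deflection
  tr <- make_sweep(v, onset_s = 0.1, duration_s = 0.12, amplitude_pA = -40)
  expect_equal(input_resistance(tr), 100)
  expect_warning(r0 <- input_resistance(make_sweep(rep(-65, n), onset_s = 0.1,
                                                   duration_s = 0.12,
                                                   amplitude_pA = -40)),
                 "Implausible")
  expect_equal(r0, 0)
  expect_error(input_resistance(tr, amplitude_pA = 0), "no step")
})

test_that("membrane tau is recovered from an exact exponential", {
  fs <- 10000
  t <- seq(0, 0.4 - 1 / fs, by = 1 / fs)
  v <- ifelse(t < 0.1, -65, -69 + 4 * exp(-(t - 0.1) * 1000 / 15))
  tr <- make_sweep(v, onset_s = 0.1, duration_s = 0.25, amplitude_pA = -40)
  tau <- membrane_tau(tr)
  expect_equal(as.numeric(tau), 15, tolerance = 0.1)
  expect_gt(attr(tau, "r_squared"), 0.999)
  # a clearly non-exponential segment is flagged as a poor fit
  v_osc <- ifelse(t < 0.1, -65, -67 + 2 * sin((t - 0.1) * 2 * pi * 40))
  expect_warning(membrane_tau(make_sweep(v_osc, onset_s = 0.1,
                                         duration_s = 0.25,
                                         amplitude_pA = -40)),
                 "Poor monoexponential")
})

test_that("sag ratio follows (Vmin - Vend)/Vmin on deflections", {
  fs <- 10000
  n <- 0.7 * fs
  t <- seq(0, length.out = n, by = 1 / fs)
  v <- rep(-65, n)
  on <- t >= 0.1 & t < 0.6
  # deflection dips to -100 mV then settles at -90 mV
  v[on] <- -65 - 100 * pmin((t[on] - 0.1) * 200, 1) +
    10 * pmin(pmax((t[on] - 0.15) * 10, 0), 1)
  tr <- make_sweep(v, onset_s = 0.1, duration_s = 0.5, amplitude_pA = -200)
  expect_equal(sag_ratio(tr), (-100 - -90) / -100, tolerance = 1e-6)
  flat <- make_sweep(rep(-65, n), onset_s = 0.1, duration_s = 0.5,
                     amplitude_pA = -200)
  expect_equal(sag_ratio(flat), 0)
  # absolute mode uses raw voltages
  expect_equal(sag_ratio(tr, mode = "absolute"), (-165 - -155) / -165,
               tolerance = 1e-6)
})

test_that("spike detection finds pasted spikes and ignores DC offsets", {
  cfg <- sim_config(seed = 71, n_cells_per_group = 2, n_genes = 200)
  ps <- generate_patchseq_cells(cfg, protocol = default_protocol(ramp_increment_pA = 50),
                                n_per_class = c(1, 1), noise_sd_mV = 0)
  s300 <- get_sweep(ps$traces, ps$truth$cell_id[1], kind = "suprathreshold_300")
  spk <- detect_spikes(s300)
  expect_equal(nrow(spk), round(ps$truth$freq_hz[1]))
  spk_dc <- detect_spikes(s300$voltage_mV + 20, fs_hz = 10000)
  expect_equal(spk_dc$index, spk$index)
  expect_equal(nrow(detect_spikes(rep(-65, 1000), fs_hz = 10000)), 0L)
})

test_that("first-AP features and spike frequency follow their definitions", {
  cfg <- sim_config(seed = 72, n_cells_per_group = 2, n_genes = 200)
  ps <- generate_patchseq_cells(cfg, protocol = default_protocol(ramp_increment_pA = 25),
                                n_per_class = c(1, 1), noise_sd_mV = 0)
  for (i in 1:2) {
    cid <- ps$truth$cell_id[i]
    ramp <- ps$traces[ps$traces$cell_id == cid &
                        ps$traces$kind == "rheobase_ramp", ]
    ap <- first_ap_features(ramp)
    expect_equal(ap$rheobase_pA, ps$truth$rheobase_pA[i])
    expect_equal(ap$spike_latency_ms, ps$truth$latency_ms[i], tolerance = 0.2)
    expect_equal(ap$ahp_mV, ps$truth$ahp_mV[i], tolerance = 0.1)
    expect_equal(ap$stdb_mV, ps$truth$stdb_mV[i], tolerance = 0.3)
    s300 <- get_sweep(ps$traces, cid, kind = "suprathreshold_300")
    expect_equal(spike_frequency(s300), ps$truth$freq_hz[i])
  }
  # duration normalization: half the spikes in half the window = same rate
  s300 <- get_sweep(ps$traces, ps$truth$cell_id[1], kind = "suprathreshold_300")
  f_half <- spike_frequency(s300, onset_s = 0.1, duration_s = 0.5)
  expect_equal(f_half, spike_frequency(s300), tolerance = 2.1)
  # no spiking sweep: features are NA
  sub <- ramp_no_spike <- ps$traces[ps$traces$cell_id == ps$truth$cell_id[1] &
                                      ps$traces$kind == "rheobase_ramp" &
                                      ps$traces$amplitude_pA <
                                        ps$truth$rheobase_pA[1], ]
  expect_true(is.na(first_ap_features(sub)$spike_latency_ms))
})

test_that("noise-free extraction recovers every planted parameter within 2%", {
  rel_err <- function(a, b) abs(a - b) / abs(b)
  errs <- c()
  for (seed in 73:75) {
    cfg <- sim_config(seed = seed, n_cells_per_group = 4, n_genes = 200)
    ps <- generate_patchseq_cells(cfg, protocol = default_protocol(ramp_increment_pA = 25),
                                  n_per_class = c(2, 2), noise_sd_mV = 0)
    f <- extract_ephys_features(ps$traces)
    tr <- ps$truth
    errs <- c(errs,
              rel_err(f$rin_MOhm, tr$rin_MOhm),
              rel_err(f$tau_ms, tr$tau_ms),
              rel_err(f$sag_ratio, tr$sag_frac),
              rel_err(f$spike_latency_ms, tr$latency_ms),
              rel_err(f$spike_freq_Hz, tr$freq_hz))
  }
  expect_lt(max(errs), 0.02)
})

test_that("patch-seq assignment applies gene and cell filters and the cutoff", {
  q <- two_class_cohort(seed = 76, n = 60)
  labels <- setNames(q$cells$true_class, q$cells$cell_id)
  resid <- regress_out_covariate(log_rpm(q, 1e4),
                                 as.numeric(factor(q$cells$age)))
  sig <- select_conserved_signature(resid, labels, counts = q,
                                    n_per_class = 150)
  cfg <- sim_config(seed = 76, n_cells_per_group = 60, n_genes = 2000,
                    marker_log_fc = 2)
  ps <- generate_patchseq_cells(cfg, protocol = default_protocol(ramp_increment_pA = 50),
                                n_per_class = c(5, 5))
  expr <- ps$expr
  # a signature gene detected in no cell is removed before scoring
  g_kill <- signature_genes(sig, "Dock5")[1]
  expr$counts[g_kill, ] <- 0
  asg <- assign_patchseq_subtype(expr, sig)
  det <- Matrix::rowMeans(expr$counts[unique(sig$genes$gene), ] > 0)
  expect_equal(unique(asg$n_kept_genes), sum(det >= 0.10))
  expect_false(g_kill %in% names(det[det >= 0.10]))
  # a cell expressing almost none of the kept genes is discarded
  expr2 <- ps$expr
  kept <- names(det[det >= 0.10])
  expr2$counts[kept, 1] <- 0
  asg2 <- assign_patchseq_subtype(expr2, sig)
  expect_equal(asg2$label[1], "DISCARDED")
  # decision cutoff: |d| must exceed 0.2
  fake <- asg
  expect_true(all(abs(asg$decision[asg$label %in% sig$classes]) > 0.2,
                  na.rm = TRUE))
  expect_true(all(abs(asg$decision[asg$label == "NON_ASSIGNED"]) <= 0.2))
})

test_that("patch-seq cohorts are assigned to the correct planted subtype", {
  cfg <- sim_config(seed = 77, n_cells_per_group = 120)
  q <- generate_query_cohort(cfg, classes = c("Dock5", "Lsp1"),
                             frac_low_quality = 0)
  labels <- setNames(q$cells$true_class, q$cells$cell_id)
  resid <- regress_out_covariate(log_rpm(q, 1e4),
                                 as.numeric(factor(q$cells$age)))
  sig <- select_conserved_signature(resid, labels, counts = q,
                                    n_per_class = 150)
  ps <- generate_patchseq_cells(cfg, protocol = default_protocol(ramp_increment_pA = 25))
  asg <- assign_patchseq_subtype(ps$expr, sig)
  expect_gte(mean(asg$label == ps$truth$true_class), 0.9)
  expect_lte(mean(!asg$label %in% c("Dock5", "Lsp1")), 0.10)
})

test_that("ephys PCA: correlated features, separability, sign convention", {
  set.seed(10)
  f <- tibble::tibble(cell_id = sprintf("c%02d", 1:40),
                      a = rnorm(40))
  f$b <- f$a                                  # perfectly correlated pair
  p <- ephys_pca(f, cols = c("a", "b"))
  expect_equal(abs(p$loadings$PC1), c(1, 1) / sqrt(2), tolerance = 1e-8)
  expect_lt(p$var_ratio[2], 1e-8)
  # constant feature dropped with warning
  f$c <- 1
  expect_warning(ephys_pca(f, cols = c("a", "b", "c")), "constant")
  # two-class preset features separate linearly in PC space
  cfg <- sim_config(seed = 78, n_cells_per_group = 4, n_genes = 200)
  ps <- generate_patchseq_cells(cfg, protocol = default_protocol(ramp_increment_pA = 25))
  feats <- extract_ephys_features(ps$traces)
  pe <- ephys_pca(feats, cols = c("rin_MOhm", "tau_ms", "sag_ratio",
                                  "spike_latency_ms", "ahp_mV", "stdb_mV",
                                  "spike_freq_Hz"))
  df <- data.frame(y = as.numeric(ps$truth$true_class == "Dock5"),
                   pe$scores[, c("PC1", "PC2")])
  fit <- suppressWarnings(glm(y ~ PC1 + PC2, data = df, family = binomial))
  acc <- mean((predict(fit, type = "response") > 0.5) == df$y)
  expect_gte(acc, 0.9)
  # deterministic up to the fixed sign convention
  pe2 <- ephys_pca(feats, cols = c("rin_MOhm", "tau_ms", "sag_ratio",
                                   "spike_latency_ms", "ahp_mV", "stdb_mV",
                                   "spike_freq_Hz"))
  expect_equal(pe$scores, pe2$scores)
})

test_that("gene-feature correlations are exact and null-calibrated", {
  set.seed(11)
  n <- 50
  feats <- tibble::tibble(cell_id = sprintf("c%02d", 1:n),
                          lat = rnorm(n))
  # a pseudo-gene equal to the feature correlates perfectly
  expr <- rbind(pseudo = feats$lat, noise = rnorm(n))
  colnames(expr) <- feats$cell_id
  res <- gene_ephys_correlation(expr, feats, cols = "lat")
  expect_equal(res$r[res$gene == "pseudo"], 1, tolerance = 1e-12)
  expect_lt(abs(res$r[res$gene == "noise"]), 0.35)
  # null p-values roughly uniform over repeated draws
  ps <- replicate(200, {
    e <- matrix(rnorm(n), 1, dimnames = list("g", feats$cell_id))
    gene_ephys_correlation(e, feats, cols = "lat")$p
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
  # zero-variance gene yields NA with warning
  e0 <- matrix(1, 1, n, dimnames = list("flat", feats$cell_id))
  expect_warning(res0 <- gene_ephys_correlation(e0, feats, cols = "lat"),
                 "Zero-variance")
  expect_true(is.na(res0$r))
})

test_that("depth correlates: chi-squared residuals match the closed form", {
  # contingency [[10, 0], [0, 10]] -> residuals +/- sqrt(5)
  f <- tibble::tibble(cell_id = sprintf("c%02d", 1:20),
                      x = c(rep(0, 10), rep(1, 10)))
  depth <- c(rep(10, 10), rep(110, 10))
  res <- depth_correlates(f, depth, layer_boundaries = c(0, 100), cols = "x")
  expect_equal(sort(unique(round(abs(res$residuals$residual), 3))),
               round(sqrt(5), 3))
  expect_equal(res$correlations$r, 1, tolerance = 1e-12)
  # depth-independent feature: small correlation in most null draws
  set.seed(12)
  rs <- replicate(60, {
    fi <- tibble::tibble(cell_id = sprintf("c%02d", 1:50), v = rnorm(50))
    d <- runif(50, 0, 600)
    depth_correlates(fi, d, layer_boundaries = c(0, 300), cols = "v")$correlations$r
  })
  expect_gte(mean(abs(rs) < 0.28), 0.95)  # |r| below the n=50 null band
})

test_that("planted latency-depth slope is recovered as a positive correlation", {
  cfg <- sim_config(seed = 79, n_cells_per_group = 30, n_genes = 200)
  ps <- generate_patchseq_cells(cfg, protocol = default_protocol(ramp_increment_pA = 25),
                                n_per_class = c(15, 15),
                                depth_latency_slope = 60)
  feats <- extract_ephys_features(ps$traces)
  one <- ps$truth$true_class == "Dock5"
  r <- cor(feats$spike_latency_ms[one], ps$truth$true_depth[one])
  expect_gt(r, 0)
})

test_that("subtype comparison matches the hand-derived Welch statistic", {
  f <- tibble::tibble(cell_id = sprintf("c%d", 1:6), v = c(1, 2, 3, 4, 5, 6))
  labs <- rep(c("a", "b"), each = 3)
  res <- compare_subtypes(f, labs, cols = "v")
  expect_equal(res$t, -3.674, tolerance = 1e-3)
  expect_equal(res$mean_a, 2)
  expect_equal(res$mean_b, 5)
  # identical groups: t = 0, p = 1
  f2 <- tibble::tibble(cell_id = sprintf("c%d", 1:6), v = rep(c(1, 2, 3), 2))
  res2 <- compare_subtypes(f2, labs, cols = "v")
  expect_equal(res2$t, 0)
  expect_equal(res2$p, 1)
  expect_error(compare_subtypes(f, c("a", "a", "a", "a", "a", "b"), cols = "v"),
               "at least 2")
})
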