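# Config-driven end-to-end run on synthetic data:
# simulate -> qc -> transfer -> signature -> trajectory -> ephys -> spatial.

#' Default pipeline configuration
#'
#' Nested list of stage parameters mirroring each module's options. Unknown
#' keys in overrides are rejected so typos fail loudly.
#'
#' @param seed Root seed; every stage draws from its own substream.
#' @param overrides Named list of stage overrides, e.g.
#'   `list(simulate = list(n_cells_per_group = 100))`.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L, overrides = list()) {
  cfg <- list(
    seed = as.integer(seed),
    simulate = list(n_cells_per_group = 120L, n_genes = 1500L,
                    n_markers_per_class = 20L, marker_log_fc = 1.5,
                    dropout_rate = 0.1, library_size_mean = 20000,
                    age_effect_size = 1.0, noise_dispersion = 0.5,
                    classes = c("Dock5", "Lsp1", "Other"),
                    ages = c("P15", "P30"),
                    embryonic_t_star = 0.4, embryonic_n_cells = 400L,
                    patchseq_n_per_class = c(20L, 27L),
                    ramp_increment_pA = 15,
                    position_shift = 120),
    qc = list(platform = "postnatal_c1"),
    transfer = list(k = 15L, n_dims = 20L, method = "cca_like"),
    signature = list(n_per_class = 150L, cost = 100),
    trajectory = list(var_fraction = 0.03, span = 0.25,
                      pseudogene_percentile = 80),
    ephys = list(min_decision = 0.2),
    spatial = list(layer_boundaries = c(0, 100, 300, 500),
                   region_limits = c(0, 1000))
  )
  merge_cfg <- function(base, over, path = "") {
    for (k in names(over)) {
      if (!k %in% names(base)) {
        abort(sprintf("Unknown config key '%s%s'.", path, k))
      }
      base[[k]] <- if (is.list(base[[k]]) && is.list(over[[k]])) {
        merge_cfg(base[[k]], over[[k]], paste0(path, k, "$"))
      } else over[[k]]
    }
    base
  }
  structure(merge_cfg(cfg, overrides), class = "pipeline_config")
}

#' Run the full synthetic pipeline
#'
#' Chains the modules end-to-end on generated data: simulate the reference
#' atlas, postnatal query cohort, embryonic continuum, patch-seq cohort and
#' laminar positions; apply platform QC; consensus label transfer;
#' age-regressed signature selection; embryonic trajectory reconstruction
#' and pseudogene thresholding; ephys feature extraction, subtype
#' assignment and subtype comparison; spatial statistics. When `out_dir` is
#' given, stage artifacts are written (TSV/JSON/MTX) together with a
#' manifest recording the seed, configuration and artifact list.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory.
#' @return Named list of stage results (invisible content also on disk when
#'   `out_dir` is set).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  if (!inherits(config, "pipeline_config")) {
    abort("`config` must come from pipeline_config().")
  }
  s <- config$simulate
  mk_cfg <- function(stream) {
    sim_config(seed = substream_seed(config$seed, stream),
               n_cells_per_group = s$n_cells_per_group,
               n_genes = s$n_genes,
               n_markers_per_class = s$n_markers_per_class,
               marker_log_fc = s$marker_log_fc,
               dropout_rate = s$dropout_rate,
               library_size_mean = s$library_size_mean,
               age_effect_size = s$age_effect_size,
               noise_dispersion = s$noise_dispersion)
  }
  # one config: all cohorts share the gene baseline and marker layout,
  # while each generator draws from its own named substream
  cfg <- mk_cfg("pipeline")
  atlas <- generate_reference_atlas(cfg, s$classes)
  query <- generate_query_cohort(cfg, s$classes, s$ages)
  embryo <- generate_embryonic_continuum(cfg, t_star = s$embryonic_t_star,
                                         classes = s$classes[1:2],
                                         n_cells = s$embryonic_n_cells)
  patch <- generate_patchseq_cells(
    cfg, protocol = default_protocol(ramp_increment_pA = s$ramp_increment_pA),
    classes = s$classes[1:2], n_per_class = s$patchseq_n_per_class)
  positions <- generate_positions(cfg, shift = s$position_shift)

  qc <- apply_cell_qc(query, preset_thresholds(config$qc$platform))
  query_qc <- qc$counts

  emb <- embed_joint(atlas, query_qc, n_dims = config$transfer$n_dims,
                     method = config$transfer$method)
  ref_labels <- setNames(atlas$cells$true_class, atlas$cells$cell_id)
  knn <- knn_classify(emb, ref_labels, k = config$transfer$k)
  svm <- train_linear_svm(atlas, ref_labels)
  svm_pred <- predict(svm, query_qc)
  assignments <- consensus_assign(
    knn, svm_pred,
    fluorescence = query_qc$cells[, c("cell_id", "tdtom")],
    tdtom_classes = s$classes[1:2])

  core <- assignments %>%
    filter(.data$core, .data$consensus_label %in% s$classes[1:2])
  core_cells <- subset_cells(query_qc, core$cell_id)
  core_labels <- setNames(core$consensus_label, core$cell_id)
  lognorm <- log_rpm(core_cells, 1e4)
  age_idx <- as.numeric(factor(core_cells$cells$age, levels = s$ages))
  resid <- regress_out_covariate(lognorm, age_idx)
  signature <- select_conserved_signature(
    resid, core_labels, counts = core_cells,
    n_per_class = min(config$signature$n_per_class, floor(n_genes(core_cells) / 2)),
    cost = config$signature$cost)

  trajectory <- reconstruct_maturation(
    embryo, var_fraction = config$trajectory$var_fraction,
    span = config$trajectory$span)
  conserved <- signature_genes(signature, s$classes[1])
  pseudo <- pseudogene_score(embryo, conserved,
                             percentile = config$trajectory$pseudogene_percentile)

  feats <- extract_ephys_features(patch$traces)
  ps_assign <- assign_patchseq_subtype(patch$expr, signature,
                                       min_decision = config$ephys$min_decision)
  subtype_tests <- compare_subtypes(
    feats, patch$truth$true_class,
    cols = c("rin_MOhm", "tau_ms", "sag_ratio", "spike_latency_ms",
             "ahp_mV", "stdb_mV", "spike_freq_Hz"))

  norm_pos <- normalize_positions(positions,
                                  region_limits = config$spatial$region_limits,
                                  jitter_seed = substream_seed(config$seed, "jitter"))
  ks <- ks_compare(norm_pos$depth[norm_pos$group == "A"],
                   norm_pos$depth[norm_pos$group == "B"])
  layers <- layer_fractions(norm_pos$depth, config$spatial$layer_boundaries,
                            list(A = norm_pos$group == "A",
                                 B = norm_pos$group == "B"))

  results <- list(config = config, atlas = atlas, query = query_qc,
                  qc_report = qc$report, assignments = assignments,
                  assignment_summary = summarize_assignments(assignments),
                  signature = signature, trajectory = trajectory,
                  pseudogene = pseudo, ephys_features = feats,
                  patchseq_assignment = ps_assign,
                  patchseq_truth = patch$truth,
                  subtype_tests = subtype_tests, positions = norm_pos,
                  ks = ks, layer_fractions = layers)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_counts_mtx(query_qc, file.path(out_dir, "query_qc"))
    artifacts <- c(
      assignments = "assignments.tsv", signature = "signature.tsv",
      trajectory = "pseudotime.tsv", pseudogene = "pseudogene.tsv",
      ephys_features = "ephys_features.tsv",
      patchseq_assignment = "patchseq_assignment.tsv",
      subtype_tests = "subtype_tests.tsv", positions = "positions.tsv",
      qc_report = "qc_report.json")
    readr::write_tsv(assignments, file.path(out_dir, "assignments.tsv"))
    readr::write_tsv(tidy(signature), file.path(out_dir, "signature.tsv"))
    readr::write_tsv(tidy(trajectory), file.path(out_dir, "pseudotime.tsv"))
    readr::write_tsv(pseudo, file.path(out_dir, "pseudogene.tsv"))
    readr::write_tsv(feats, file.path(out_dir, "ephys_features.tsv"))
    readr::write_tsv(ps_assign, file.path(out_dir, "patchseq_assignment.tsv"))
    readr::write_tsv(subtype_tests, file.path(out_dir, "subtype_tests.tsv"))
    readr::write_tsv(norm_pos, file.path(out_dir, "positions.tsv"))
    jsonlite::write_json(qc$report, file.path(out_dir, "qc_report.json"),
                         auto_unbox = TRUE, digits = NA)
    manifest <- list(
      seed = config$seed,
      config = unclass(config),
      created = format(Sys.time(), tz = "UTC"),
      artifacts = c("query_qc/matrix.mtx", unname(artifacts)),
      transition = trajectory$transition,
      ks_D = ks$D)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(results)
}
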