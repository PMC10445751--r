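# Configuration for the synthetic-data generators.

#' Simulation configuration
#'
#' One configuration object drives every generator. Identical configurations
#' yield bit-identical outputs; each generator draws from its own seed
#' substream (see [substream_seed()]).
#'
#' @param seed Integer root seed.
#' @param n_cells_per_group Cells per class (or per group, per age, ...).
#' @param n_genes Number of genes in the simulated transcriptome.
#' @param n_markers_per_class Planted marker genes per class.
#' @param marker_log_fc Natural-log shift applied to a class's marker means.
#' @param dropout_rate Probability that any observed count is independently
#'   zeroed, emulating dropout.
#' @param library_size_mean Mean per-cell library size (counts).
#' @param age_effect_size Additive log-scale shift per age index on the
#'   designated age-gene block.
#' @param noise_dispersion Negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2). Zero requests the noise-free limit, in which
#'   expected values are returned exactly.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_cells_per_group = 200L,
                       n_genes = 2000L,
                       n_markers_per_class = 20L,
                       marker_log_fc = 1.5,
                       dropout_rate = 0.1,
                       library_size_mean = 20000,
                       age_effect_size = 1.0,
                       noise_dispersion = 0.5) {
  cfg <- list(seed = as.integer(seed),
              n_cells_per_group = as.integer(n_cells_per_group),
              n_genes = as.integer(n_genes),
              n_markers_per_class = as.integer(n_markers_per_class),
              marker_log_fc = marker_log_fc,
              dropout_rate = dropout_rate,
              library_size_mean = library_size_mean,
              age_effect_size = age_effect_size,
              noise_dispersion = noise_dispersion)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg, n_classes = NULL) {
  chk <- function(ok, field, msg) {
    if (!ok) abort(sprintf("Invalid `%s`: %s", field, msg),
                   class = "ngc_parameter_error")
  }
  chk(length(cfg$seed) == 1 && is.finite(cfg$seed), "seed", "must be a finite integer")
  chk(cfg$n_cells_per_group >= 1, "n_cells_per_group", "must be >= 1")
  chk(cfg$n_genes >= 1, "n_genes", "must be >= 1")
  chk(cfg$n_markers_per_class >= 0, "n_markers_per_class", "must be >= 0")
  chk(is.finite(cfg$marker_log_fc), "marker_log_fc", "must be finite")
  chk(cfg$dropout_rate >= 0 && cfg$dropout_rate <= 1, "dropout_rate",
      "must lie in [0, 1]")
  chk(cfg$library_size_mean > 0, "library_size_mean", "must be positive")
  chk(is.finite(cfg$age_effect_size), "age_effect_size", "must be finite")
  chk(cfg$noise_dispersion >= 0, "noise_dispersion", "must be >= 0")
  if (!is.null(n_classes)) {
    chk(cfg$n_markers_per_class * n_classes <= cfg$n_genes,
        "n_markers_per_class", "marker blocks exceed the gene universe")
  }
  invisible(cfg)
}
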