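# Per-platform cell quality control and marker-based removal of non-target
# populations.

#' Platform QC presets
#'
#' Thresholds per sequencing platform. Postnatal C1: exclude cells expressing
#' <1000 genes, <100,000 UMIs or <50,000 mapped reads, or with >20%
#' mitochondrial reads. Embryonic C1: the same but >15% mitochondrial.
#' Droplet: <1000 genes or >15% mitochondrial (UMI/read rules inactive).
#' Patch-seq: keep cells with at least 10,000 sequenced reads, >=25%
#' exonically mapped, <15% mitochondrial and confirmed fluorescence.
#' Boundaries are strict exclusions, so a cell exactly at a bound is kept.
#'
#' @param platform One of `"postnatal_c1"`, `"embryonic_c1"`, `"droplet"`,
#'   `"patchseq"`.
#' @return A `qc_thresholds` list: `min_genes`, `min_umis`,
#'   `min_mapped_reads`, `max_mito_fraction`, `min_exonic_fraction`,
#'   `require_fluorescence`. Inactive rules are `NA`.
#' @export
preset_thresholds <- function(platform) {
  presets <- list(
    postnatal_c1 = list(min_genes = 1000L, min_umis = 100000L,
                        min_mapped_reads = 50000L, max_mito_fraction = 0.20,
                        min_exonic_fraction = NA_real_,
                        require_fluorescence = FALSE),
    embryonic_c1 = list(min_genes = 1000L, min_umis = 100000L,
                        min_mapped_reads = 50000L, max_mito_fraction = 0.15,
                        min_exonic_fraction = NA_real_,
                        require_fluorescence = FALSE),
    droplet = list(min_genes = 1000L, min_umis = NA_integer_,
                   min_mapped_reads = NA_integer_, max_mito_fraction = 0.15,
                   min_exonic_fraction = NA_real_,
                   require_fluorescence = FALSE),
    patchseq = list(min_genes = NA_integer_, min_umis = NA_integer_,
                    min_mapped_reads = 10000L, max_mito_fraction = 0.15,
                    min_exonic_fraction = 0.25,
                    require_fluorescence = TRUE)
  )
  if (!platform %in% names(presets)) {
    abort(sprintf("Unknown platform '%s'. Known: %s.", platform,
                  paste(names(presets), collapse = ", ")))
  }
  structure(presets[[platform]], class = "qc_thresholds", platform = platform)
}

#' Apply cell-level quality control
#'
#' Keeps exactly the cells passing every active rule. Exclusion bounds are
#' strict: a cell is removed when genes < `min_genes`, UMIs < `min_umis`,
#' reads < `min_mapped_reads`, mitochondrial fraction > `max_mito_fraction`,
#' exonic fraction < `min_exonic_fraction`, or (when fluorescence is
#' required) `tdtom & gfp` is not TRUE. Counts are never mutated, only
#' subset.
#'
#' @param counts An `ngc_counts` whose cell metadata carries the metric
#'   columns each active rule needs (`n_genes`, `n_umis`, `n_reads`,
#'   `mito_fraction`, `exonic_fraction`, `tdtom`/`gfp`).
#' @param thresholds A `qc_thresholds` (see [preset_thresholds()]).
#' @return List with `counts` (kept cells) and `report` (tibble: `n_input`,
#'   `n_kept`, plus per-rule exclusion counts; rules may overlap, `n_kept`
#'   comes from the joint mask).
#' @export
apply_cell_qc <- function(counts, thresholds) {
  md <- counts$cells
  need <- function(col, rule_active) {
    if (rule_active && !col %in% names(md)) {
      abort(sprintf("QC requires metadata column '%s', which is missing.", col))
    }
  }
  th <- thresholds
  active <- list(
    genes = !is.na(th$min_genes), umis = !is.na(th$min_umis),
    reads = !is.na(th$min_mapped_reads), mito = !is.na(th$max_mito_fraction),
    exonic = !is.na(th$min_exonic_fraction),
    fluorescence = isTRUE(th$require_fluorescence)
  )
  need("n_genes", active$genes); need("n_umis", active$umis)
  need("n_reads", active$reads); need("mito_fraction", active$mito)
  need("exonic_fraction", active$exonic)
  if (active$fluorescence) { need("tdtom", TRUE); need("gfp", TRUE) }
  n <- nrow(md)
  fail <- list(
    genes = if (active$genes) md$n_genes < th$min_genes else rep(FALSE, n),
    umis = if (active$umis) md$n_umis < th$min_umis else rep(FALSE, n),
    reads = if (active$reads) md$n_reads < th$min_mapped_reads else rep(FALSE, n),
    mito = if (active$mito) md$mito_fraction > th$max_mito_fraction else rep(FALSE, n),
    exonic = if (active$exonic) md$exonic_fraction < th$min_exonic_fraction else rep(FALSE, n),
    fluorescence = if (active$fluorescence) !(md$tdtom & md$gfp) else rep(FALSE, n)
  )
  keep <- !Reduce(`|`, fail)
  report <- tibble(
    n_input = n, n_kept = sum(keep),
    excluded_genes = sum(fail$genes), excluded_umis = sum(fail$umis),
    excluded_reads = sum(fail$reads), excluded_mito = sum(fail$mito),
    excluded_exonic = sum(fail$exonic),
    excluded_fluorescence = sum(fail$fluorescence)
  )
  attr(report, "kept_cell_ids") <- md$cell_id[keep]
  list(counts = subset_cells(counts, which(keep)), report = report)
}

#' Flag non-target populations by marker-panel scoring of clusters
#'
#' Clusters cells on the top `n_var_genes` variable genes (k-means on the
#' leading principal components of log-normalized expression, seeded), then
#' flags every cluster whose mean panel score (average normalized expression
#' of the panel genes) exceeds the global mean score by `factor`. Cells in
#' unflagged clusters are labeled `"target"`.
#'
#' @param counts An `ngc_counts`.
#' @param marker_panels Named list of gene vectors, one per non-target
#'   population (e.g. `list(glutamatergic = c(...))`).
#' @param n_var_genes Number of variable genes for clustering (default 2000).
#' @param n_clusters Number of k-means clusters (default 8, capped at
#'   cells/2).
#' @param factor Flagging factor on the global mean panel score (default 2).
#' @param seed Seed for the clustering.
#' @return Tibble (`cell_id`, `cluster`, `flag`).
#' @export
flag_non_target_populations <- function(counts, marker_panels,
                                        n_var_genes = 2000, n_clusters = 8,
                                        factor = 2, seed = 1L) {
  if (length(marker_panels) == 0) abort("`marker_panels` must be non-empty.")
  if (n_clusters >= n_cells(counts)) {
    abort("Fewer cells than clusters requested.")
  }
  lognorm <- log_rpm(counts, scale = 1e4)
  vg <- variable_genes(lognorm, n_var_genes)
  x <- t(scale(t(lognorm[vg, , drop = FALSE])))
  x[!is.finite(x)] <- 0
  pcs <- with_seed(substream_seed(seed, "flag-pca"), {
    p <- prcomp(t(x), center = FALSE, rank. = min(20, ncol(x) - 1, nrow(x)))
    p$x
  })
  cl <- with_seed(substream_seed(seed, "flag-kmeans"),
                  kmeans(pcs, centers = n_clusters, nstart = 10,
                         iter.max = 50)$cluster)
  flag <- rep("target", n_cells(counts))
  for (pop in names(marker_panels)) {
    panel <- intersect(marker_panels[[pop]], rownames(lognorm))
    if (length(panel) == 0) next
    score <- colMeans(lognorm[panel, , drop = FALSE])
    global <- mean(score)
    cl_means <- tapply(score, cl, mean)
    hot <- as.integer(names(cl_means)[cl_means > factor * global])
    flag[cl %in% hot] <- pop
  }
  tibble(cell_id = counts$cells$cell_id, cluster = as.integer(cl), flag = flag)
}
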