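# Embryonic maturation reconstruction: PCA -> principal curve -> oriented
# 0-1 maturation score -> mitotic transition; pseudogene lineage scoring;
# pseudotime-regressed differential expression.

#' PCA keeping components above a variance-ratio floor
#'
#' Principal components explaining at least `var_fraction` of the variance
#' are retained (at least one always is), in decreasing-variance order.
#'
#' @param mat Cells x features numeric matrix, already normalized/scaled as
#'   desired (for the embryonic pipeline: log-normalized, residualized
#'   against the number of genes expressed, gene-scaled).
#' @param var_fraction Variance-ratio floor (default 0.03).
#' @return List `pc_coords` (cells x kept PCs), `n_kept`, `var_ratio` (all
#'   PCs).
#' @export
pca_keep <- function(mat, var_fraction = 0.03) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 2 || ncol(mat) < 2) abort("Need at least 2 cells and 2 features.")
  p <- prcomp(mat, center = TRUE, scale. = FALSE)
  total <- sum(p$sdev^2)
  if (!is.finite(total) || total <= 0) abort("Degenerate matrix: zero variance.")
  vr <- p$sdev^2 / total
  n_kept <- max(1L, sum(vr >= var_fraction))
  list(pc_coords = p$x[, seq_len(n_kept), drop = FALSE],
       n_kept = n_kept, var_ratio = vr)
}

#' Orient an arc-length parameterization and scale it to \[0, 1\]
#'
#' The direction of the curve is chosen so that maturation correlates more
#' with the late (Dcx-like) marker mean than with the early (Nes-like)
#' marker mean, then min-max scaled to \[0, 1\].
#'
#' @param lambda Per-cell arc length from [fit_principal_curve()].
#' @param nes_mean Per-cell mean expression of early markers.
#' @param dcx_mean Per-cell mean expression of late markers.
#' @return Numeric vector of maturation scores in \[0, 1\].
#' @export
orient_and_scale <- function(lambda, nes_mean, dcx_mean) {
  if (sd(lambda) == 0) abort("Degenerate arc length: all values equal.")
  c_dcx <- cor(lambda, dcx_mean)
  c_nes <- cor(lambda, nes_mean)
  if (is.na(c_dcx) || is.na(c_nes) || c_dcx == c_nes) {
    abort("Marker correlations equal or undefined; orientation must be set explicitly.")
  }
  if (c_dcx < c_nes) lambda <- -lambda
  (lambda - min(lambda)) / (max(lambda) - min(lambda))
}

#' Cell-cycle (S-G2/M) score
#'
#' Unweighted mean of log-normalized expression over a cell-cycle gene list.
#'
#' @param expr `ngc_counts` or log-normalized gene x cell matrix.
#' @param sg2m_genes Cell-cycle gene ids.
#' @return Named numeric vector, one score per cell.
#' @export
cell_cycle_score <- function(expr, sg2m_genes) {
  mat <- if (inherits(expr, "ngc_counts")) log_rpm(expr) else as.matrix(expr)
  present <- intersect(sg2m_genes, rownames(mat))
  if (length(present) == 0) abort("No listed cell-cycle gene present.")
  colMeans(mat[present, , drop = FALSE])
}

#' Locate the mitotic-to-postmitotic transition
#'
#' Fits a local regression (loess) of the S-G2/M score against maturation
#' and returns the smallest maturation at which the fitted curve falls below
#' half the mean score and stays below through the next fitted point
#' (sustained crossing, guarding against local-regression wiggle).
#'
#' @param maturation Per-cell maturation in \[0, 1\].
#' @param sg2m_score Per-cell S-G2/M score.
#' @param span,degree Loess parameters (defaults 0.25 and 1).
#' @param n_grid Evaluation grid size (default 200).
#' @return List `transition` (maturation value), `half_average`, `fit`
#'   (tibble maturation, fitted), `crossed` (FALSE on the warning path).
#' @export
find_mitotic_transition <- function(maturation, sg2m_score, span = 0.25,
                                    degree = 1, n_grid = 200) {
  if (length(maturation) < 20) abort("Need at least 20 cells.")
  half <- mean(sg2m_score) / 2
  lo <- loess(sg2m_score ~ maturation, span = span, degree = degree)
  grid <- seq(min(maturation), max(maturation), length.out = n_grid)
  fitted_vals <- predict(lo, newdata = data.frame(maturation = grid))
  below <- fitted_vals < half
  sustained <- which(below[-length(below)] & below[-1])
  if (all(below, na.rm = TRUE)) {
    warn("Fitted curve lies entirely below the half average; transition set to 0.")
    transition <- 0; crossed <- FALSE
  } else if (length(sustained) == 0) {
    warn("Fitted curve never falls below the half average; transition set to 1.")
    transition <- 1; crossed <- FALSE
  } else {
    transition <- grid[sustained[1]]; crossed <- TRUE
  }
  list(transition = transition, half_average = half,
       fit = tibble(maturation = grid, fitted = fitted_vals),
       crossed = crossed)
}

#' Reconstruct the embryonic maturation trajectory
#'
#' End-to-end convenience wrapper: log-normalize, residualize against the
#' number of genes expressed, scale genes, PCA with the variance floor, fit
#' the principal curve, orient by early/late markers, scale maturation to
#' \[0, 1\], score the cell cycle and locate the mitotic transition.
#'
#' @param counts An `ngc_counts`.
#' @param nes_genes,dcx_genes,sg2m_genes Marker gene sets (defaults: the
#'   generator's planted roles when present in the gene metadata).
#' @param var_fraction PC variance floor (default 0.03).
#' @param span,degree Loess parameters for the transition fit.
#' @param n_var_genes Variable genes used for the PCA (default 675).
#' @return An `ngc_pseudotime` object: tibble-backed result with per-cell
#'   `pc_coords`, `lambda`, `maturation`, `sg2m_score`, `is_mitotic`, plus
#'   `transition`, `curve`, `converged`.
#' @export
reconstruct_maturation <- function(counts, nes_genes = NULL, dcx_genes = NULL,
                                   sg2m_genes = NULL, var_fraction = 0.03,
                                   span = 0.25, degree = 1,
                                   n_var_genes = 675) {
  role <- counts$genes$role %||% rep("none", n_genes(counts))
  pick <- function(given, r) {
    if (!is.null(given)) given else counts$genes$gene_id[role == r]
  }
  nes_genes <- pick(nes_genes, "nes")
  dcx_genes <- pick(dcx_genes, "dcx")
  sg2m_genes <- pick(sg2m_genes, "sg2m")
  if (!length(nes_genes) || !length(dcx_genes) || !length(sg2m_genes)) {
    abort("Marker gene sets (nes/dcx/sg2m) must be provided or recorded in gene metadata.")
  }
  lognorm <- log_rpm(counts, 1e4)
  resid <- regress_out_covariate(lognorm, colSums(counts$counts > 0))
  vg <- unique(c(variable_genes(resid, n_var_genes),
                 nes_genes, dcx_genes, sg2m_genes))
  x <- t(scale(t(resid[vg, , drop = FALSE])))
  x[!is.finite(x)] <- 0
  pcs <- pca_keep(t(x), var_fraction = var_fraction)
  pc <- fit_principal_curve(pcs$pc_coords)
  nes_mean <- colMeans(lognorm[intersect(nes_genes, rownames(lognorm)), , drop = FALSE])
  dcx_mean <- colMeans(lognorm[intersect(dcx_genes, rownames(lognorm)), , drop = FALSE])
  maturation <- orient_and_scale(pc$lambda, nes_mean, dcx_mean)
  sg2m <- cell_cycle_score(lognorm, sg2m_genes)
  tr <- find_mitotic_transition(maturation, sg2m, span = span, degree = degree)
  cells <- tibble(cell_id = counts$cells$cell_id,
                  lambda = pc$lambda,
                  maturation = maturation,
                  sg2m_score = unname(sg2m),
                  is_mitotic = maturation < tr$transition)
  structure(list(cells = cells, pc_coords = pcs$pc_coords,
                 n_pcs_kept = pcs$n_kept, curve = pc$curve,
                 transition = tr$transition, transition_fit = tr$fit,
                 half_average = tr$half_average, converged = pc$converged),
            class = "ngc_pseudotime")
}

#' @export
print.ngc_pseudotime <- function(x, ...) {
  cat(sprintf("<ngc_pseudotime> %d cells, %d PCs kept, transition at %.3f\n",
              nrow(x$cells), x$n_pcs_kept, x$transition))
  invisible(x)
}

#' @export
tidy.ngc_pseudotime <- function(x, ...) x$cells

#' @export
glance.ngc_pseudotime <- function(x, ...) {
  tibble(n_cells = nrow(x$cells), n_pcs_kept = x$n_pcs_kept,
         transition = x$transition, pct_mitotic = 100 * mean(x$cells$is_mitotic),
         converged = x$converged)
}

#' Pseudogene lineage score and percentile thresholding
#'
#' The pseudogene score of a cell is the mean normalized expression of a
#' conserved marker set divided by the number of genes the cell expresses;
#' cells at or above the configured percentile of the score distribution are
#' assigned to the lineage. The percentile threshold uses the upper
#' nearest-rank convention, so with distinct scores the assigned fraction is
#' `1 - percentile/100` exactly.
#'
#' @param expr An `ngc_counts`.
#' @param gene_set Conserved marker genes.
#' @param percentile Assignment percentile (default 80).
#' @return Tibble (`cell_id`, `score`, `assigned`) with attribute
#'   `threshold`; cells expressing zero genes are dropped with a warning.
#' @export
pseudogene_score <- function(expr, gene_set, percentile = 80) {
  present <- intersect(gene_set, rownames(expr$counts))
  if (length(present) == 0) abort("No pseudogene-set gene present.")
  lognorm <- log_rpm(expr)
  n_expressed <- colSums(expr$counts > 0)
  ok <- n_expressed > 0
  if (any(!ok)) {
    warn(sprintf("%d cell(s) express zero genes; excluded.", sum(!ok)))
  }
  score <- colMeans(lognorm[present, ok, drop = FALSE]) / n_expressed[ok]
  threshold <- upper_nearest_rank(score, percentile)
  out <- tibble(cell_id = expr$cells$cell_id[ok],
                score = unname(score),
                assigned = score >= threshold)
  attr(out, "threshold") <- threshold
  out
}

#' Maturation-regressed differential expression between two classes
#'
#' Removes a linear maturation effect from each gene, then tests the two
#' classes on the residuals with a Wilcoxon rank-sum test and
#' Benjamini-Hochberg correction. Classes must span overlapping maturation
#' ranges, otherwise the contrast is confounded and an error is raised.
#'
#' @param expr `ngc_counts` or log-normalized gene x cell matrix.
#' @param labels Named character vector mapping `cell_id` to one of two
#'   classes.
#' @param maturation Per-cell maturation (same cell order as `expr`).
#' @return Tibble (`gene`, `delta`, `statistic`, `p`, `q`) ranked by `p`;
#'   `delta` is the residual-mean difference (first class minus second).
#' @export
pseudotime_regressed_markers <- function(expr, labels, maturation) {
  mat <- if (inherits(expr, "ngc_counts")) log_rpm(expr) else as.matrix(expr)
  labs <- unname(labels[colnames(mat)])
  classes <- sort(unique(labs))
  if (length(classes) != 2) abort("Exactly two classes required.")
  r1 <- range(maturation[labs == classes[1]])
  r2 <- range(maturation[labs == classes[2]])
  if (r1[1] > r2[2] || r2[1] > r1[2]) {
    abort("Classes span non-overlapping maturation ranges (confounded).")
  }
  resid <- regress_out_covariate(mat, maturation)
  a <- labs == classes[1]
  res <- purrr::map(rownames(resid), function(g) {
    x <- resid[g, a]; yv <- resid[g, !a]
    if (sd(c(x, yv)) == 0) return(list(stat = NA_real_, p = NA_real_))
    wt <- suppressWarnings(wilcox.test(x, yv))
    list(stat = unname(wt$statistic), p = wt$p.value)
  })
  out <- tibble(gene = rownames(resid),
                delta = rowMeans(resid[, a, drop = FALSE]) -
                  rowMeans(resid[, !a, drop = FALSE]),
                statistic = map_dbl(res, "stat"),
                p = map_dbl(res, "p"))
  out$q <- p.adjust(out$p, method = "BH")
  arrange(out, .data$p)
}
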