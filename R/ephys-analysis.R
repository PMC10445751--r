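# Patch-seq subtype assignment and feature-level statistics.

#' Assign patch-seq cells to subtypes with a trained signature
#'
#' Restricts the signature genes to those detected in at least
#' `min_gene_cell_fraction` of the patched cells, discards cells expressing
#' fewer than `min_cell_gene_fraction` of the kept genes, computes the SVM
#' decision value on the kept genes, and assigns the class only when the
#' absolute decision value exceeds `min_decision`.
#'
#' @param expr An `ngc_counts` of patch-seq cells (QC'd with the patch-seq
#'   preset).
#' @param signature An `ngc_signature` trained on the two subtypes.
#' @param min_gene_cell_fraction Detection floor for keeping a signature
#'   gene (default 0.10).
#' @param min_cell_gene_fraction Minimum fraction of kept genes a cell must
#'   express (default 0.20).
#' @param min_decision Decision-value cutoff for assignment (default 0.2).
#' @return Tibble (`cell_id`, `decision`, `label`): `label` is one of the
#'   signature classes, `"NON_ASSIGNED"` (decision within the cutoff) or
#'   `"DISCARDED"` (cell failed the gene-detection filter, decision `NA`).
#' @export
assign_patchseq_subtype <- function(expr, signature,
                                    min_gene_cell_fraction = 0.10,
                                    min_cell_gene_fraction = 0.20,
                                    min_decision = 0.2) {
  sig_genes <- intersect(unique(signature$genes$gene), rownames(expr$counts))
  det <- Matrix::rowMeans(expr$counts[sig_genes, , drop = FALSE] > 0)
  kept <- sig_genes[det >= min_gene_cell_fraction]
  if (length(kept) == 0) abort("No signature gene passes the detection filter.")
  frac_expressed <- Matrix::colMeans(expr$counts[kept, , drop = FALSE] > 0)
  ok <- frac_expressed >= min_cell_gene_fraction
  lognorm <- log_rpm(expr, 1e4)
  w <- signature$svm$weights[kept, signature$classes[1]]
  # genes outside the kept set contribute at their training-mean level, so
  # the decision scale stays centred as in training
  omitted <- setdiff(signature$svm$genes, kept)
  b <- signature$svm$bias[signature$classes[1]] +
    sum(signature$svm$weights[omitted, signature$classes[1]] *
          signature$svm$gene_means[omitted])
  d <- drop(t(lognorm[kept, , drop = FALSE]) %*% w + b)
  label <- ifelse(d > min_decision, signature$classes[1],
                  ifelse(d < -min_decision, signature$classes[2],
                         "NON_ASSIGNED"))
  label[!ok] <- "DISCARDED"
  d[!ok] <- NA_real_
  tibble(cell_id = expr$cells$cell_id, decision = unname(d),
         label = unname(label), n_kept_genes = length(kept))
}

#' PCA of scaled electrophysiological features
#'
#' Features are z-scored and decomposed; constant features are dropped with
#' a warning and rows with missing values removed. Component signs follow
#' the convention that each PC's largest-magnitude loading is positive.
#'
#' @param features Feature tibble (e.g. from [extract_ephys_features()]);
#'   all numeric columns except `cell_id` are used unless `cols` is given.
#' @param cols Optional character vector of feature columns.
#' @return An `ngc_ephys_pca`: `scores` tibble (cell_id, PC1..), `loadings`
#'   tibble (feature, PC1..), `var_ratio`.
#' @export
ephys_pca <- function(features, cols = NULL) {
  num <- if (is.null(cols)) {
    names(features)[vapply(features, is.numeric, logical(1))]
  } else cols
  x <- as.matrix(features[, num, drop = FALSE])
  rownames(x) <- features$cell_id
  keep_rows <- stats::complete.cases(x)
  x <- x[keep_rows, , drop = FALSE]
  if (nrow(x) < 3) abort("Need at least 3 complete cells.")
  const <- apply(x, 2, sd) == 0
  if (any(const)) {
    warn(paste("Dropping constant feature(s):",
               paste(colnames(x)[const], collapse = ", ")))
    x <- x[, !const, drop = FALSE]
  }
  p <- prcomp(x, center = TRUE, scale. = TRUE)
  flip <- vapply(seq_len(ncol(p$rotation)), function(j) {
    sign(p$rotation[which.max(abs(p$rotation[, j])), j])
  }, numeric(1))
  p$rotation <- sweep(p$rotation, 2, flip, "*")
  p$x <- sweep(p$x, 2, flip, "*")
  structure(list(
    scores = dplyr::bind_cols(tibble(cell_id = rownames(x)), as_tibble(p$x)),
    loadings = dplyr::bind_cols(tibble(feature = colnames(x)),
                                as_tibble(p$rotation)),
    var_ratio = p$sdev^2 / sum(p$sdev^2)
  ), class = "ngc_ephys_pca")
}

#' @export
print.ngc_ephys_pca <- function(x, ...) {
  cat(sprintf("<ngc_ephys_pca> %d cells, %d features; PC1 %.0f%%, PC2 %.0f%%\n",
              nrow(x$scores), nrow(x$loadings),
              100 * x$var_ratio[1], 100 * x$var_ratio[2]))
  invisible(x)
}

#' Gene-feature Pearson correlation matrix
#'
#' Pearson r and two-sided p per gene x feature pair, with
#' Benjamini-Hochberg q-values across all pairs. Zero-variance genes or
#' features yield `NA` entries with a warning.
#'
#' @param expr `ngc_counts` or log-normalized gene x cell matrix (restrict
#'   to a functional gene list upstream).
#' @param features Feature tibble with `cell_id` matching the expression
#'   cells.
#' @param cols Optional feature columns.
#' @return Long tibble (`gene`, `feature`, `r`, `p`, `q`).
#' @export
gene_ephys_correlation <- function(expr, features, cols = NULL) {
  mat <- if (inherits(expr, "ngc_counts")) log_rpm(expr) else as.matrix(expr)
  if (!setequal(colnames(mat), features$cell_id)) {
    abort("Expression and feature tables cover different cells.")
  }
  features <- features[match(colnames(mat), features$cell_id), ]
  num <- if (is.null(cols)) {
    setdiff(names(features)[vapply(features, is.numeric, logical(1))], "n_kept_genes")
  } else cols
  warned <- FALSE
  out <- purrr::map(rownames(mat), function(g) {
    gx <- mat[g, ]
    purrr::map(num, function(f) {
      fx <- features[[f]]
      ok <- is.finite(fx)
      if (sd(gx[ok]) == 0 || sum(ok) < 3 || sd(fx[ok]) == 0) {
        warned <<- TRUE
        return(tibble(gene = g, feature = f, r = NA_real_, p = NA_real_))
      }
      ct <- cor.test(gx[ok], fx[ok], method = "pearson")
      tibble(gene = g, feature = f, r = unname(ct$estimate), p = ct$p.value)
    }) %>% dplyr::bind_rows()
  }) %>% dplyr::bind_rows()
  if (warned) warn("Zero-variance gene/feature pair(s) set to NA.")
  out$q <- p.adjust(out$p, method = "BH")
  out
}

#' Depth correlates of electrophysiological features
#'
#' Pearson r of each feature against radial depth, plus a per-layer
#' chi-squared analysis: cells are split at the feature median (low/high)
#' and cross-tabulated against depth layers; Pearson residuals
#' (observed - expected) / sqrt(expected) are returned.
#'
#' @param features Feature tibble.
#' @param depth Per-cell depth (same order as `features`).
#' @param layer_boundaries Increasing depth boundaries; depths beyond the
#'   last boundary fall in an overflow layer.
#' @param cols Optional feature columns.
#' @return List: `correlations` tibble (`feature`, `r`, `p`), `residuals`
#'   long tibble (`feature`, `level`, `layer`, `residual`); empty layers are
#'   dropped with a warning.
#' @export
depth_correlates <- function(features, depth, layer_boundaries,
                             cols = NULL) {
  num <- if (is.null(cols)) {
    setdiff(names(features)[vapply(features, is.numeric, logical(1))], "n_kept_genes")
  } else cols
  layer <- cut(depth, breaks = c(layer_boundaries, Inf), right = FALSE)
  if (any(table(layer) == 0)) {
    warn("Empty layer bin(s) dropped.")
    layer <- droplevels(layer)
  }
  cors <- purrr::map(num, function(f) {
    fx <- features[[f]]
    ok <- is.finite(fx)
    if (sd(fx[ok]) == 0) return(tibble(feature = f, r = NA_real_, p = NA_real_))
    ct <- cor.test(fx[ok], depth[ok])
    tibble(feature = f, r = unname(ct$estimate), p = ct$p.value)
  }) %>% dplyr::bind_rows()
  res <- purrr::map(num, function(f) {
    fx <- features[[f]]
    ok <- is.finite(fx)
    lev <- ifelse(fx[ok] > median(fx[ok]), "high", "low")
    tab <- table(lev, droplevels(layer[ok]))
    if (any(dim(tab) < 2)) return(NULL)
    r <- suppressWarnings(chisq.test(tab)$residuals)
    as_tibble(as.data.frame(r)) %>%
      rename(level = "lev", layer = 2, residual = "Freq") %>%
      mutate(feature = f, .before = 1)
  }) %>% dplyr::bind_rows()
  list(correlations = cors, residuals = res)
}

#' Compare features between two subtypes
#'
#' Two-sided unpaired t-test per feature (Welch by default), with group
#' means and standard errors.
#'
#' @param features Feature tibble.
#' @param labels Per-cell subtype labels (same order), two groups.
#' @param cols Optional feature columns.
#' @param var_equal Use the pooled-variance Student test instead of Welch.
#' @return Tibble (`feature`, `mean_a`, `sem_a`, `mean_b`, `sem_b`, `t`,
#'   `df`, `p`); group a is the first label alphabetically.
#' @export
compare_subtypes <- function(features, labels, cols = NULL,
                             var_equal = FALSE) {
  groups <- sort(unique(labels))
  if (length(groups) != 2) abort("Exactly two groups required.")
  if (any(table(labels) < 2)) abort("Each group needs at least 2 cells.")
  num <- if (is.null(cols)) {
    setdiff(names(features)[vapply(features, is.numeric, logical(1))], "n_kept_genes")
  } else cols
  purrr::map(num, function(f) {
    a <- features[[f]][labels == groups[1]]
    b <- features[[f]][labels == groups[2]]
    a <- a[is.finite(a)]; b <- b[is.finite(b)]
    sem <- function(x) sd(x) / sqrt(length(x))
    if (length(a) < 2 || length(b) < 2 || (sd(a) == 0 && sd(b) == 0)) {
      ident <- length(a) >= 2 && length(b) >= 2 && mean(a) == mean(b)
      return(tibble(feature = f, mean_a = mean(a), sem_a = sem(a),
                    mean_b = mean(b), sem_b = sem(b),
                    t = if (ident) 0 else NA_real_,
                    df = NA_real_, p = if (ident) 1 else NA_real_))
    }
    tt <- t.test(a, b, var.equal = var_equal)
    tibble(feature = f, mean_a = mean(a), sem_a = sem(a),
           mean_b = mean(b), sem_b = sem(b),
           t = unname(tt$statistic), df = unname(tt$parameter),
           p = tt$p.value)
  }) %>% dplyr::bind_rows()
}
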