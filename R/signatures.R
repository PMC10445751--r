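# Time-conserved class signatures via age-regressed overfit linear-SVM
# feature selection, and conserved-marker intersection with z-scores.

#' Select a conserved two-class signature by overfit SVM feature selection
#'
#' Fits a linear SVM on all cells (deliberately overfit: train = test, high
#' cost), ranks genes by signed weight, and takes the top `n_per_class`
#' genes per class. Log1p-RPM fold changes are computed from the raw counts
#' and linearly min-max rescaled onto \[-0.5, 0.5\] for display.
#'
#' @param expr Residual (e.g. age-regressed, see [regress_out_covariate()])
#'   log-normalized gene x cell matrix used for the SVM fit.
#' @param labels Named character vector mapping `cell_id` to one of two
#'   classes.
#' @param counts An `ngc_counts` with the raw counts for fold-change
#'   computation (defaults to using `expr` as the expression scale).
#' @param n_per_class Genes selected per class (default 150).
#' @param cost Soft-margin cost; high by design to overfit (default 100).
#' @return An `ngc_signature`: tibble-backed object with fields `classes`,
#'   `genes` (tibble gene, class, weight, log_fc, rescaled_fc), `svm`.
#' @export
select_conserved_signature <- function(expr, labels, counts = NULL,
                                       n_per_class = 150, cost = 100) {
  mat <- as.matrix(expr)
  classes <- sort(unique(unname(labels[colnames(mat)])))
  if (length(classes) != 2) abort("Signature selection is two-class.")
  if (n_per_class > nrow(mat) / 2) {
    abort("`n_per_class` exceeds half the gene universe.")
  }
  svm <- train_linear_svm(mat, labels, regularization = cost)
  w <- svm$weights[, classes[1]]
  ord <- order(w, decreasing = TRUE)
  top_a <- rownames(mat)[ord[seq_len(n_per_class)]]
  top_b <- rownames(mat)[rev(ord)[seq_len(n_per_class)]]
  fc_mat <- if (!is.null(counts)) log_rpm(counts) else mat
  labs_fc <- unname(labels[colnames(fc_mat)])
  log_fc <- rowMeans(fc_mat[, labs_fc == classes[1], drop = FALSE]) -
    rowMeans(fc_mat[, labs_fc == classes[2], drop = FALSE])
  sel <- c(top_a, top_b)
  fc_sel <- log_fc[sel]
  rescaled <- rescale_fc(fc_sel)
  genes <- tibble(gene = sel,
                  class = rep(classes, each = n_per_class),
                  weight = w[sel],
                  log_fc = fc_sel,
                  rescaled_fc = rescaled)
  structure(list(classes = classes, genes = genes, svm = svm,
                 n_per_class = n_per_class),
            class = "ngc_signature")
}

# Linear min-max map of a signed FC vector onto [-0.5, 0.5].
rescale_fc <- function(fc) {
  rng <- range(fc)
  if (diff(rng) == 0) return(rep(0, length(fc)))
  (fc - rng[1]) / diff(rng) - 0.5
}

#' @export
print.ngc_signature <- function(x, ...) {
  cat(sprintf("<ngc_signature> %s vs %s, %d genes per class\n",
              x$classes[1], x$classes[2], x$n_per_class))
  invisible(x)
}

#' @export
tidy.ngc_signature <- function(x, ...) x$genes

#' @export
glance.ngc_signature <- function(x, ...) {
  tibble(class_a = x$classes[1], class_b = x$classes[2],
         n_genes = nrow(x$genes), n_per_class = x$n_per_class,
         cost = x$svm$cost)
}

#' Signature gene list for one class
#' @param signature An `ngc_signature`.
#' @param class Class label (defaults to the first class).
#' @return Character vector of genes.
#' @export
signature_genes <- function(signature, class = signature$classes[1]) {
  signature$genes$gene[signature$genes$class == class]
}

#' Intersect a postnatal signature with embryonically expressed genes
#'
#' Keeps the genes of the signature's target-class list that are expressed
#' above `min_log_rpm` (mean log1p-RPM) in the embryonic data, and computes,
#' for each kept gene, the z-score of the target-population mean against the
#' non-target distribution separately in the embryonic and postnatal data.
#'
#' @param signature An `ngc_signature`; its first class (or `class`) is the
#'   conserved set of interest.
#' @param embryonic An `ngc_counts` of embryonic cells.
#' @param embryonic_flag Logical vector marking embryonic target-lineage
#'   cells (e.g. pseudogene-assigned).
#' @param postnatal An `ngc_counts` of postnatal cells.
#' @param postnatal_flag Logical vector marking postnatal target cells.
#' @param class Signature class to intersect (default first).
#' @param min_log_rpm Embryonic expression floor (default 0.05 log RPM).
#' @return Tibble (`gene`, `mean_log_rpm_embryonic`, `z_embryonic`,
#'   `z_postnatal`); empty (with a warning) when nothing intersects.
#' @export
intersect_time_conserved <- function(signature, embryonic, embryonic_flag,
                                     postnatal, postnatal_flag,
                                     class = signature$classes[1],
                                     min_log_rpm = 0.05) {
  genes <- signature_genes(signature, class)
  emb <- log_rpm(embryonic)
  post <- log_rpm(postnatal)
  genes <- intersect(genes, rownames(emb))
  keep <- genes[rowMeans(emb[genes, , drop = FALSE]) > min_log_rpm]
  if (length(keep) == 0) {
    warn("No signature gene is expressed embryonically above the floor.")
    return(tibble(gene = character(), mean_log_rpm_embryonic = double(),
                  z_embryonic = double(), z_postnatal = double()))
  }
  # z of the target mean against the sampling distribution of the
  # background mean: (mean_tgt - mean_bg) / (sd_bg / sqrt(n_bg))
  zscore <- function(m, flag, gs) {
    gs <- intersect(gs, rownames(m))
    tgt <- rowMeans(m[gs, flag, drop = FALSE])
    bg <- m[gs, !flag, drop = FALSE]
    mu <- rowMeans(bg)
    se <- apply(bg, 1, sd) / sqrt(ncol(bg))
    out <- ifelse(se > 0, (tgt - mu) / se, 0)
    setNames(out, gs)
  }
  z_emb <- zscore(emb, embryonic_flag, keep)
  z_post <- zscore(post, postnatal_flag, keep)
  tibble(gene = keep,
         mean_log_rpm_embryonic = rowMeans(emb[keep, , drop = FALSE]),
         z_embryonic = unname(z_emb[keep]),
         z_postnatal = unname(z_post[keep]))
}
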