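# Consensus label transfer: joint embedding, kNN classifier, linear SVM,
# consensus with fluorescence-consistency core calls.

#' Embed reference and query cells in one coordinate system
#'
#' `cca_like` (default): the shared variable genes are standardized per
#' dataset (removing dataset-specific location and scale, a documented
#' approximation of canonical-correlation integration) and a single PCA is
#' fitted on the concatenated cells; robust to dataset-level shifts such as
#' age programs present only in the query. `pca_project`: PCA is fitted on
#' the reference's log-normalized variable genes and the query is projected
#' with the reference's centering and rotation.
#'
#' @param reference,query `ngc_counts` objects sharing gene ids.
#' @param n_dims Number of embedding dimensions (default 20).
#' @param method `"pca_project"` or `"cca_like"`.
#' @param n_var_genes Variable genes used (default 2000).
#' @return Tibble (`cell_id`, `origin`, `PC1..PCn`) of class
#'   `ngc_embedding`.
#' @export
embed_joint <- function(reference, query, n_dims = 20,
                        method = c("cca_like", "pca_project"),
                        n_var_genes = 2000) {
  method <- match.arg(method)
  shared <- intersect(rownames(reference$counts), rownames(query$counts))
  if (length(shared) == 0) abort("Reference and query share no genes.")
  if (length(shared) < 50) abort("Fewer than 50 shared genes.")
  n_dims <- min(n_dims, n_cells(reference) - 1, n_cells(query) - 1)
  ref_ln <- log_rpm(reference, 1e4)[shared, , drop = FALSE]
  qry_ln <- log_rpm(query, 1e4)[shared, , drop = FALSE]
  vg <- variable_genes(ref_ln, n_var_genes)
  ref_ln <- ref_ln[vg, , drop = FALSE]
  qry_ln <- qry_ln[vg, , drop = FALSE]
  if (method == "pca_project") {
    p <- prcomp(t(ref_ln), center = TRUE, scale. = FALSE, rank. = n_dims)
    ref_coords <- p$x[, seq_len(n_dims), drop = FALSE]
    qry_coords <- scale(t(qry_ln), center = p$center, scale = FALSE) %*%
      p$rotation[, seq_len(n_dims), drop = FALSE]
  } else {
    std <- function(m) {
      z <- t(scale(t(m)))
      z[!is.finite(z)] <- 0
      z
    }
    joint <- cbind(std(ref_ln), std(qry_ln))
    p <- prcomp(t(joint), center = TRUE, scale. = FALSE, rank. = n_dims)
    ref_coords <- p$x[seq_len(ncol(ref_ln)), , drop = FALSE]
    qry_coords <- p$x[ncol(ref_ln) + seq_len(ncol(qry_ln)), , drop = FALSE]
  }
  coords <- rbind(ref_coords, qry_coords)
  colnames(coords) <- paste0("PC", seq_len(ncol(coords)))
  out <- dplyr::bind_cols(
    tibble(cell_id = c(reference$cells$cell_id, query$cells$cell_id),
           origin = rep(c("reference", "query"),
                        c(n_cells(reference), n_cells(query)))),
    as_tibble(coords)
  )
  class(out) <- c("ngc_embedding", class(out))
  out
}

embedding_coords <- function(embedding) {
  as.matrix(embedding[, grep("^PC", names(embedding)), drop = FALSE])
}

#' k-nearest-neighbour classification on an embedding
#'
#' Majority label among the k nearest reference cells (Euclidean). Ties are
#' broken in favour of the single nearest neighbour's label.
#'
#' @param embedding An `ngc_embedding` from [embed_joint()].
#' @param ref_labels Named character vector mapping reference `cell_id` to
#'   class label.
#' @param k Number of neighbours (default 15).
#' @return Tibble (`cell_id`, `knn_label`, `knn_vote_fraction`).
#' @export
knn_classify <- function(embedding, ref_labels, k = 15) {
  ref <- embedding[embedding$origin == "reference", ]
  qry <- embedding[embedding$origin == "query", ]
  if (nrow(ref) == 0) abort("Empty reference in embedding.")
  if (k < 1 || k > nrow(ref)) abort("`k` must lie in [1, n reference cells].")
  labs <- unname(ref_labels[ref$cell_id])
  if (anyNA(labs)) abort("`ref_labels` is missing labels for some reference cells.")
  nn <- FNN::get.knnx(embedding_coords(ref), embedding_coords(qry), k = k)
  res <- purrr::map(seq_len(nrow(qry)), function(i) {
    nl <- labs[nn$nn.index[i, ]]
    tab <- table(nl)
    top <- names(tab)[tab == max(tab)]
    win <- if (length(top) == 1) top else nl[1]  # tie: nearest neighbour
    list(label = win, vote = max(tab) / k)
  })
  tibble(cell_id = qry$cell_id,
         knn_label = map_chr(res, "label"),
         knn_vote_fraction = map_dbl(res, "vote"))
}

#' Train a one-vs-rest linear SVM on log-normalized expression
#'
#' Soft-margin linear SVM per class against the rest; exposes per-gene
#' weights, biases and signed decision values. For two classes a single
#' binary machine is fitted and mirrored.
#'
#' @param expr An `ngc_counts` (log-normalized internally at scale 1e4) or
#'   a gene x cell matrix already log-normalized.
#' @param labels Named character vector mapping `cell_id` to class.
#' @param regularization Soft-margin cost C (default 1).
#' @param genes Optional gene subset to train on.
#' @return An `ngc_svm` object with `classes`, `weights` (genes x classes),
#'   `bias`, `genes`, `cost`.
#' @export
train_linear_svm <- function(expr, labels, regularization = 1, genes = NULL) {
  mat <- if (inherits(expr, "ngc_counts")) log_rpm(expr, 1e4) else as.matrix(expr)
  if (!is.null(genes)) mat <- mat[intersect(genes, rownames(mat)), , drop = FALSE]
  labs <- unname(labels[colnames(mat)])
  if (anyNA(labs)) abort("`labels` missing for some cells.")
  classes <- sort(unique(labs))
  if (length(classes) < 2) abort("Need at least two classes to train an SVM.")
  if (any(table(labs) < 2)) abort("Every class needs at least two cells.")
  x <- t(mat)
  fit_binary <- function(y) {
    m <- e1071::svm(x, factor(y, levels = c("pos", "rest")),
                    kernel = "linear", cost = regularization, scale = FALSE)
    w <- drop(crossprod(m$coefs, m$SV))
    b <- -m$rho
    # libsvm orients the machine by the first training label; flip so that
    # positive decision means "pos"
    pred <- drop(x %*% w + b)
    if (cor(pred, as.numeric(y == "pos")) < 0) { w <- -w; b <- -b }
    list(w = w, b = b)
  }
  if (length(classes) == 2) {
    f <- fit_binary(ifelse(labs == classes[1], "pos", "rest"))
    weights <- cbind(f$w, -f$w)
    bias <- c(f$b, -f$b)
  } else {
    fits <- purrr::map(classes, function(cl) {
      fit_binary(ifelse(labs == cl, "pos", "rest"))
    })
    weights <- do.call(cbind, purrr::map(fits, "w"))
    bias <- map_dbl(fits, "b")
  }
  dimnames(weights) <- list(rownames(mat), classes)
  names(bias) <- classes
  structure(list(classes = classes, weights = weights, bias = bias,
                 genes = rownames(mat), gene_means = rowMeans(mat),
                 cost = regularization),
            class = "ngc_svm")
}

#' Decision values and labels from an `ngc_svm`
#'
#' @param object An `ngc_svm`.
#' @param expr `ngc_counts` or log-normalized gene x cell matrix.
#' @param ... Unused.
#' @return Tibble (`cell_id`, `svm_label`, `svm_decision`): the winning
#'   one-vs-rest class and its margin.
#' @export
predict.ngc_svm <- function(object, expr, ...) {
  mat <- if (inherits(expr, "ngc_counts")) log_rpm(expr, 1e4) else as.matrix(expr)
  common <- intersect(object$genes, rownames(mat))
  if (length(common) == 0) abort("No model genes present in the input.")
  d <- t(mat[common, , drop = FALSE]) %*%
    object$weights[common, , drop = FALSE]
  omitted <- setdiff(object$genes, common)
  offset <- object$bias +
    drop(crossprod(object$weights[omitted, , drop = FALSE],
                   object$gene_means[omitted]))
  d <- sweep(d, 2, offset, "+")
  win <- max.col(d, ties.method = "first")
  tibble(cell_id = colnames(mat),
         svm_label = object$classes[win],
         svm_decision = d[cbind(seq_len(nrow(d)), win)])
}

#' @export
print.ngc_svm <- function(x, ...) {
  cat(sprintf("<ngc_svm> %d classes (%s), %d genes, C=%g\n",
              length(x$classes), paste(x$classes, collapse = ", "),
              length(x$genes), x$cost))
  invisible(x)
}

#' @export
tidy.ngc_svm <- function(x, ...) {
  as_tibble(x$weights, rownames = "gene") %>%
    tidyr::pivot_longer(-"gene", names_to = "class", values_to = "weight")
}

#' Consensus assignment between kNN and SVM classifiers
#'
#' Agreement between the two classifiers gives the consensus label;
#' disagreement gives `"INCONCLUSIVE"`. A consensus cell whose label
#' contradicts its fluorescence-implied lineage is kept but demoted to
#' `core = FALSE`; consistent cells are `core = TRUE`.
#'
#' @param knn Tibble from [knn_classify()].
#' @param svm Tibble from [predict.ngc_svm()].
#' @param fluorescence Optional tibble (`cell_id`, `tdtom`).
#' @param tdtom_classes Classes implied by tdTOM+ lineage; a tdTOM- cell
#'   assigned to one of these (or a tdTOM+ cell assigned outside) is not
#'   core.
#' @return Tibble (`cell_id`, `knn_label`, `knn_vote_fraction`, `svm_label`,
#'   `svm_decision`, `consensus_label`, `core`).
#' @export
consensus_assign <- function(knn, svm, fluorescence = NULL,
                             tdtom_classes = NULL) {
  if (!setequal(knn$cell_id, svm$cell_id)) {
    abort("kNN and SVM results cover different cell sets.")
  }
  out <- dplyr::inner_join(knn, svm, by = "cell_id") %>%
    mutate(consensus_label = ifelse(.data$knn_label == .data$svm_label,
                                    .data$knn_label, "INCONCLUSIVE"))
  out$core <- out$consensus_label != "INCONCLUSIVE"
  if (!is.null(fluorescence) && !is.null(tdtom_classes)) {
    fl <- fluorescence[match(out$cell_id, fluorescence$cell_id), ]
    implied <- out$consensus_label %in% tdtom_classes
    contradict <- !is.na(fl$tdtom) & out$core & (implied != fl$tdtom)
    out$core[contradict] <- FALSE
  }
  out
}

#' Summarize a consensus assignment table
#'
#' Per-label counts and percentages over all cells, plus the overall
#' assignment rate.
#'
#' @param assignments Tibble from [consensus_assign()], or any tibble with a
#'   `consensus_label` column.
#' @return Tibble (`label`, `n`, `pct`) where `pct` is over all cells;
#'   attribute `assigned_pct` holds the total percentage of non-inconclusive
#'   cells.
#' @export
summarize_assignments <- function(assignments) {
  n_total <- nrow(assignments)
  out <- assignments %>%
    count(label = .data$consensus_label) %>%
    mutate(pct = 100 * .data$n / n_total) %>%
    arrange(desc(.data$n))
  attr(out, "assigned_pct") <-
    100 * sum(assignments$consensus_label != "INCONCLUSIVE") / n_total
  out
}

#' Seeded per-cluster enrichment of a flagged population
#'
#' For each cluster, the percentage of flagged cells within a seeded uniform
#' sample of `sample_size` cells. When the smallest cluster is below
#' `sample_size`, the sample size is lowered to the smallest cluster size so
#' all clusters are sampled equally.
#'
#' @param cluster_labels Tibble (`cell_id`, `cluster`).
#' @param group_flag Named logical vector (or tibble `cell_id`, `flag`)
#'   marking the population of interest.
#' @param sample_size Cells sampled per cluster (default 95).
#' @param seed Integer seed.
#' @return Tibble (`cluster`, `sample_size`, `pct_flagged`).
#' @export
cluster_group_enrichment <- function(cluster_labels, group_flag,
                                     sample_size = 95, seed = 1L) {
  if (is.data.frame(group_flag)) {
    group_flag <- setNames(group_flag$flag, group_flag$cell_id)
  }
  sizes <- table(cluster_labels$cluster)
  if (any(sizes == 0) || nrow(cluster_labels) == 0) abort("Empty cluster.")
  eff <- min(sample_size, min(sizes))
  with_seed(substream_seed(seed, "cluster-enrichment"), {
    cluster_labels %>%
      group_by(.data$cluster) %>%
      summarise(sample_size = eff,
                pct_flagged = {
                  ids <- sample(.data$cell_id, eff)
                  100 * mean(group_flag[ids])
                }, .groups = "drop")
  })
}
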