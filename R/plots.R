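# ggplot2 views of the main result types.

#' @importFrom ggplot2 ggplot aes geom_point geom_line geom_hline geom_vline
#'   geom_segment labs theme_minimal autoplot
NULL

#' @export
ggplot2::autoplot

#' Plot a joint embedding
#'
#' @param object An `ngc_embedding` from [embed_joint()].
#' @param labels Optional named vector of cell labels for colouring.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ngc_embedding <- function(object, labels = NULL, ...) {
  df <- as_tibble(object)
  df$label <- if (is.null(labels)) df$origin else unname(labels[df$cell_id])
  ggplot(df, aes(x = .data$PC1, y = .data$PC2,
                 colour = .data$label, shape = .data$origin)) +
    geom_point(alpha = 0.7, size = 1.5) +
    labs(x = "PC1", y = "PC2", colour = NULL, shape = NULL) +
    theme_minimal()
}

#' Plot the maturation trajectory diagnostics
#'
#' S-G2/M score against maturation with the loess fit, the half-average
#' level and the detected mitotic transition.
#'
#' @param object An `ngc_pseudotime` from [reconstruct_maturation()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ngc_pseudotime <- function(object, ...) {
  ggplot(object$cells, aes(x = .data$maturation, y = .data$sg2m_score)) +
    geom_point(aes(colour = .data$is_mitotic), alpha = 0.6, size = 1) +
    geom_line(data = object$transition_fit,
              aes(x = .data$maturation, y = .data$fitted),
              inherit.aes = FALSE, linewidth = 0.8) +
    geom_hline(yintercept = object$half_average, linetype = 2) +
    geom_vline(xintercept = object$transition, linetype = 3) +
    labs(x = "maturation score", y = "S-G2/M score",
         colour = "mitotic") +
    theme_minimal()
}

#' Biplot of an electrophysiology PCA
#'
#' Cell scores with feature loading vectors.
#'
#' @param object An `ngc_ephys_pca` from [ephys_pca()].
#' @param labels Optional per-cell labels for colouring.
#' @param loading_scale Multiplier applied to the loading vectors.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ngc_ephys_pca <- function(object, labels = NULL, loading_scale = 3,
                                   ...) {
  sc <- object$scores
  sc$label <- if (is.null(labels)) "cell" else labels
  ld <- object$loadings
  ggplot(sc, aes(x = .data$PC1, y = .data$PC2)) +
    geom_point(aes(colour = .data$label), size = 2, alpha = 0.8) +
    geom_segment(data = ld,
                 aes(x = 0, y = 0, xend = .data$PC1 * loading_scale,
                     yend = .data$PC2 * loading_scale),
                 inherit.aes = FALSE,
                 arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm"))) +
    ggplot2::geom_text(data = ld,
                       aes(x = .data$PC1 * loading_scale * 1.1,
                           y = .data$PC2 * loading_scale * 1.1,
                           label = .data$feature),
                       inherit.aes = FALSE, size = 3) +
    labs(colour = NULL) +
    theme_minimal()
}

#' Laminar density profiles per group
#'
#' @param depths_by_group Named list of depth vectors.
#' @param bandwidth Passed to [density_profile()].
#' @return A ggplot with depth on the y axis (pia at the top), as laminar
#'   distributions are conventionally drawn.
#' @export
plot_depth_density <- function(depths_by_group, bandwidth = "auto") {
  df <- purrr::imap(depths_by_group, function(d, nm) {
    density_profile(d, bandwidth) %>% mutate(group = nm)
  }) %>% dplyr::bind_rows()
  ggplot(df, aes(x = .data$density, y = .data$depth, colour = .data$group)) +
    geom_line() +
    ggplot2::scale_y_reverse() +
    labs(y = "depth from pia", x = "density", colour = NULL) +
    theme_minimal()
}

#' Volcano-style view of a signature
#'
#' Rescaled fold change against SVM weight for the selected genes.
#'
#' @param object An `ngc_signature`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ngc_signature <- function(object, ...) {
  ggplot(object$genes, aes(x = .data$rescaled_fc, y = .data$weight,
                           colour = .data$class)) +
    geom_point(alpha = 0.7, size = 1.2) +
    labs(x = "rescaled log1p-RPM fold change", y = "SVM weight",
         colour = NULL) +
    theme_minimal()
}
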