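# Synthetic laminar positions and gene-annotation maps.

#' Generate laminar position samples from two shifted distributions
#'
#' Two groups of cells receive depths from normal distributions whose
#' locations differ by `shift`; a per-image landmark offset is added to the
#' raw coordinate so that landmark normalization is exercised downstream.
#'
#' @param config A [sim_config()]; `n_cells_per_group` cells per group.
#' @param shift Location shift (same units as depth, default um) between the
#'   two groups.
#' @param depth_mean,depth_sd Baseline depth distribution of group A.
#' @param n_images Number of images the cells are spread across, each with
#'   its own landmark coordinate.
#' @return Tibble (`cell_id`, `x_raw`, `y_raw`, `landmark`, `image`,
#'   `group`, `true_depth`).
#' @export
generate_positions <- function(config, shift = 0, depth_mean = 200,
                               depth_sd = 60, n_images = 3) {
  n <- config$n_cells_per_group
  with_seed(substream_seed(config$seed, "positions"), {
    group <- rep(c("A", "B"), each = n)
    depth <- pmax(0, rnorm(2 * n, depth_mean + (group == "B") * shift, depth_sd))
    image <- sample(seq_len(n_images), 2 * n, replace = TRUE)
    landmark <- runif(n_images, 100, 400)[image]
    tibble(cell_id = sprintf("pos_%04d", seq_len(2 * n)),
           x_raw = runif(2 * n, 0, 1000),
           y_raw = landmark + depth,
           landmark = landmark,
           image = image,
           group = group,
           true_depth = depth)
  })
}

#' Generate a random gene-annotation map with one planted term
#'
#' Each gene receives a Poisson number of random term memberships; one
#' designated term is planted to cover exactly a given gene set. Terms are
#' linked by a random parent map that is acyclic by construction (each term
#' may only point to an earlier term).
#'
#' @param genes Character vector: the gene universe.
#' @param n_terms Number of random terms.
#' @param planted_term Optional list `list(name =, genes =)`; the planted
#'   genes must lie in the universe.
#' @param seed Integer seed.
#' @param mean_terms_per_gene Mean random memberships per gene.
#' @return List with `gene2term` (tibble gene, term), `parents` (tibble term,
#'   parent), `universe`.
#' @export
generate_annotation_map <- function(genes, n_terms = 50, planted_term = NULL,
                                    seed = 1L, mean_terms_per_gene = 3) {
  if (!is.null(planted_term) && !all(planted_term$genes %in% genes)) {
    abort("Planted term contains genes outside the universe.")
  }
  with_seed(substream_seed(seed, "annotation"), {
    terms <- sprintf("T%03d", seq_len(n_terms))
    k <- rpois(length(genes), mean_terms_per_gene)
    gene2term <- tibble(
      gene = rep(genes, k),
      term = unlist(purrr::map(k, function(ki) sample(terms, ki, replace = FALSE)))
    ) %>% distinct()
    if (!is.null(planted_term)) {
      gene2term <- dplyr::bind_rows(
        gene2term,
        tibble(gene = planted_term$genes, term = planted_term$name)
      ) %>% distinct()
    }
    all_terms <- unique(gene2term$term)
    # acyclic parent map: term i may only have a parent with smaller index
    parents <- tibble(term = all_terms[-1],
                      parent = all_terms[pmax(1, floor(runif(length(all_terms) - 1) *
                                                         (seq_along(all_terms)[-1] - 1)) + 1)])
    list(gene2term = gene2term, parents = parents, universe = genes)
  })
}
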