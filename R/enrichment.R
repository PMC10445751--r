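# Hypergeometric gene-set over-representation with optional ancestor
# propagation over a term DAG.

# Close each gene's term memberships over the parent map (transitively).
propagate_terms <- function(gene2term, parents) {
  if (is.null(parents) || nrow(parents) == 0) return(gene2term)
  parent_of <- split(parents$parent, parents$term)
  close_terms <- function(terms) {
    seen <- unique(terms)
    frontier <- seen
    while (length(frontier)) {
      nxt <- unique(unlist(parent_of[frontier], use.names = FALSE))
      nxt <- setdiff(nxt, seen)
      seen <- c(seen, nxt)
      frontier <- nxt
    }
    seen
  }
  split(gene2term$term, gene2term$gene) %>%
    purrr::imap(function(terms, g) tibble(gene = g, term = close_terms(terms))) %>%
    dplyr::bind_rows()
}

#' Hypergeometric gene-set enrichment
#'
#' One-sided over-representation per term: p = P\[X >= k\] with X
#' hypergeometric on the universe of expressed genes (N), term size (K) and
#' query size (n). With `propagate_ancestors` each gene's terms are closed
#' over the parent map before counting, so ancestor terms accumulate their
#' descendants' genes. Benjamini-Hochberg q-values are appended across
#' terms.
#'
#' @param query Character vector of genes; must be a subset of the universe.
#' @param annotation List with `gene2term` (tibble gene, term), optional
#'   `parents` (tibble term, parent), and `universe` (gene vector), as
#'   produced by [generate_annotation_map()].
#' @param propagate_ancestors Close terms over the parent DAG (default
#'   FALSE).
#' @return Tibble (`term`, `K`, `k`, `p`, `q`) sorted by `p`.
#' @export
hypergeometric_enrichment <- function(query, annotation,
                                      propagate_ancestors = FALSE) {
  universe <- unique(annotation$universe)
  if (!all(query %in% universe)) {
    abort("`query` must be a subset of the annotation universe.")
  }
  g2t <- annotation$gene2term %>% filter(.data$gene %in% universe)
  dropped <- setdiff(annotation$gene2term$gene, universe)
  if (length(dropped)) {
    warn(sprintf("%d annotated gene(s) outside the universe skipped.",
                 length(dropped)))
  }
  if (propagate_ancestors) {
    g2t <- propagate_terms(g2t, annotation$parents)
  }
  N <- length(universe)
  n <- length(unique(query))
  g2t %>%
    distinct() %>%
    group_by(.data$term) %>%
    summarise(K = dplyr::n_distinct(.data$gene),
              k = dplyr::n_distinct(intersect(.data$gene, query)),
              .groups = "drop") %>%
    mutate(p = phyper(.data$k - 1, .data$K, N - .data$K, n,
                      lower.tail = FALSE),
           q = p.adjust(.data$p, method = "BH")) %>%
    arrange(.data$p)
}
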