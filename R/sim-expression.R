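# Synthetic expression generators: reference atlas, postnatal query cohort,
# embryonic maturation continuum. All counts come from one sampler: per-gene
# relative expression profiles scaled by a per-cell library size, negative
# binomial noise, then independent Bernoulli dropout.

# Draw counts around per-cell expected profiles. `log_rel` is a gene x cell
# matrix of log relative expression. In the noise-free limit
# (noise_dispersion == 0) the expected values themselves are returned and the
# library size is fixed at its mean.
sample_counts <- function(log_rel, cfg) {
  n_g <- nrow(log_rel); n_c <- ncol(log_rel)
  rel <- exp(log_rel)
  p <- sweep(rel, 2, colSums(rel), "/")
  noise_free <- cfg$noise_dispersion == 0
  libs <- if (noise_free) rep(cfg$library_size_mean, n_c)
          else cfg$library_size_mean *
            exp(rnorm(n_c, -0.3^2 / 2, 0.3))
  mu <- sweep(p, 2, libs, "*")
  counts <- if (noise_free) mu
            else matrix(rnbinom(n_g * n_c, mu = mu, size = 1 / cfg$noise_dispersion),
                        n_g, n_c)
  if (cfg$dropout_rate > 0) {
    keep <- matrix(runif(n_g * n_c) >= cfg$dropout_rate, n_g, n_c)
    counts <- counts * keep
  }
  dimnames(counts) <- dimnames(log_rel)
  counts
}

gene_ids <- function(n) sprintf("g%04d", seq_len(n))

# Baseline log relative expression shared by atlas and query under the same
# config seed, plus the planted gene-role map (class markers, age block).
base_gene_model <- function(cfg, classes, n_age_genes = 50) {
  n_classes <- length(classes)
  validate_sim_config(cfg, n_classes = n_classes)
  ids <- gene_ids(cfg$n_genes)
  base <- with_seed(substream_seed(cfg$seed, "gene-baseline"),
                    rnorm(cfg$n_genes, 0, 1))
  names(base) <- ids
  role <- rep("none", cfg$n_genes)
  m <- cfg$n_markers_per_class
  for (i in seq_len(n_classes)) {
    idx <- ((i - 1) * m + 1):(i * m)
    role[idx] <- paste0("marker_", classes[i])
  }
  needed <- n_classes * m + n_age_genes
  if (needed > cfg$n_genes) abort("Invalid `n_genes`: too small for marker and age blocks",
                                  class = "ngc_parameter_error")
  role[(n_classes * m + 1):needed] <- "age"
  # age-regulated transcripts: low baseline, induced with age, so that
  # their information is carried by the age covariate rather than by
  # residual cell-to-cell variation
  base[role == "age"] <- base[role == "age"] * 0.1 - 3.5
  list(ids = ids, base = base, role = role,
       genes = tibble(gene_id = ids, role = role))
}

# Class-specific log relative profile for one cell.
class_profile <- function(model, cfg, class) {
  lp <- model$base
  lp[model$role == paste0("marker_", class)] <-
    lp[model$role == paste0("marker_", class)] + cfg$marker_log_fc
  lp
}

#' Generate a synthetic reference atlas
#'
#' Stands in for an adult reference taxonomy: negative-binomial counts with
#' class-specific marker genes shifted up by `marker_log_fc` on the log
#' scale, per-cell library-size variation and independent dropout. Truth
#' labels are stored in the cell metadata (`true_class`).
#'
#' @param config A [sim_config()].
#' @param classes Character vector of >= 2 class labels.
#' @return An `ngc_counts`; cell metadata carries the truth table.
#' @export
generate_reference_atlas <- function(config, classes = c("Dock5", "Lsp1", "Other")) {
  if (length(classes) < 2) abort("Need at least two classes.",
                                 class = "ngc_parameter_error")
  model <- base_gene_model(config, classes)
  n <- config$n_cells_per_group
  cell_class <- rep(classes, each = n)
  with_seed(substream_seed(config$seed, "atlas"), {
    log_rel <- vapply(cell_class, function(cl) class_profile(model, config, cl),
                      numeric(config$n_genes))
    colnames(log_rel) <- sprintf("ref_%04d", seq_along(cell_class))
    rownames(log_rel) <- model$ids
    counts <- sample_counts(log_rel, config)
    cells <- tibble(cell_id = colnames(counts),
                    true_class = cell_class,
                    age = "adult",
                    platform = "reference",
                    n_genes = full_scale_genes(counts, config$n_genes),
                    n_umis = full_depth_umis(length(cell_class)),
                    n_reads = full_depth_umis(length(cell_class)) * 3L,
                    mito_fraction = stats::rbeta(length(cell_class), 2, 38))
    ngc_counts(counts, cells, model$genes)
  })
}

# Full-transcriptome QC metadata: the simulated matrix only covers a gene
# subsample, so depth and gene-detection metrics are reported at the scale
# of a real library / transcriptome.
full_depth_umis <- function(n) as.integer(round(2e5 * exp(rnorm(n, 0, 0.25))))

full_scale_genes <- function(counts, n_genes_universe) {
  as.integer(round(colSums(counts > 0) * max(1, 8000 / n_genes_universe)))
}

#' Generate a synthetic query cohort across postnatal ages
#'
#' Same marker structure as the atlas generated from the same config, plus an
#' additive age effect (`age_effect_size` x zero-based age index) on the
#' designated age-gene block. Fluorescence flags (`tdtom`) are consistent
#' with the true class.
#'
#' @param config A [sim_config()]; must match the atlas config for the marker
#'   structure to be shared.
#' @param classes Class labels (typically `unique(atlas$cells$true_class)`).
#' @param ages Ordered character vector of age labels; each (class, age) pair
#'   receives `n_cells_per_group` cells.
#' @param tdtom_classes Classes whose cells are tdTOM+ (POA lineage); others
#'   are tdTOM-.
#' @param frac_low_quality Fraction of cells planted as low quality (high
#'   mitochondrial load), exercising the QC stage (default 0.03).
#' @return An `ngc_counts` with truth and fluorescence metadata.
#' @export
generate_query_cohort <- function(config, classes = c("Dock5", "Lsp1", "Other"),
                                  ages = c("P15", "P30"),
                                  tdtom_classes = classes[seq_len(min(2, length(classes)))],
                                  frac_low_quality = 0.03) {
  if (length(ages) < 1 || anyDuplicated(ages)) {
    abort("`ages` must be a non-empty vector of unique age labels.")
  }
  model <- base_gene_model(config, classes)
  n <- config$n_cells_per_group
  grid <- expand.grid(class = classes, age = ages, stringsAsFactors = FALSE)
  cell_class <- rep(grid$class, each = n)
  cell_age <- rep(grid$age, each = n)
  age_idx <- match(cell_age, ages) - 1L
  with_seed(substream_seed(config$seed, "query"), {
    log_rel <- vapply(seq_along(cell_class), function(i) {
      lp <- class_profile(model, config, cell_class[i])
      lp[model$role == "age"] <- lp[model$role == "age"] +
        config$age_effect_size * age_idx[i]
      lp
    }, numeric(config$n_genes))
    colnames(log_rel) <- sprintf("qry_%04d", seq_along(cell_class))
    rownames(log_rel) <- model$ids
    counts <- sample_counts(log_rel, config)
    cells <- tibble(cell_id = colnames(counts),
                    true_class = cell_class,
                    age = cell_age,
                    platform = "postnatal_c1",
                    tdtom = cell_class %in% tdtom_classes,
                    gfp = TRUE,
                    n_genes = full_scale_genes(counts, config$n_genes),
                    n_umis = full_depth_umis(length(cell_class)),
                    n_reads = full_depth_umis(length(cell_class)) * 3L,
                    mito_fraction = stats::rbeta(length(cell_class), 2, 38))
    low_q <- runif(nrow(cells)) < frac_low_quality
    cells$mito_fraction[low_q] <- runif(sum(low_q), 0.25, 0.5)
    ngc_counts(counts, cells, model$genes)
  })
}

#' Generate an embryonic maturation continuum
#'
#' Cells receive a true maturation drawn uniformly on \[0, 1\]. Three gene
#' programs are planted on top of a static baseline: a cell-cycle (S-G2/M)
#' block whose expression decays to near zero beyond the transition point
#' `t_star`; an early (Nes-like) block decreasing with maturation; and a late
#' (Dcx-like) block increasing with maturation. When `classes` is given, each
#' cell is also assigned a subtype with maturation-independent marker genes,
#' so subtype discovery can be tested orthogonally to maturation.
#'
#' @param config A [sim_config()].
#' @param t_star Planted mitotic-to-postmitotic transition point.
#' @param classes Optional subtype labels to plant (e.g. `c("Dock5","Lsp1")`).
#' @param n_cells Number of cells (default `n_cells_per_group` times the
#'   number of classes, or `n_cells_per_group` when no classes).
#' @return An `ngc_counts`; cell metadata carries `true_maturation` (and
#'   `true_class` when subtypes are planted); gene metadata carries the
#'   program roles (`sg2m`, `nes`, `dcx`, `marker_*`).
#' @export
generate_embryonic_continuum <- function(config, t_star = 0.4, classes = NULL,
                                         n_cells = NULL) {
  n_classes <- length(classes)
  validate_sim_config(config, n_classes = max(1L, n_classes))
  if (is.null(n_cells)) n_cells <- config$n_cells_per_group * max(1L, n_classes)
  # shared baseline and marker layout with the postnatal generators, so
  # conserved markers are the same gene ids across epochs
  model <- base_gene_model(config, classes %||% character(0))
  role <- model$role
  n_prog <- 10L + 20L + 20L + 150L
  free <- which(role == "none")
  if (length(free) < n_prog) {
    abort("Invalid `n_genes`: too small for program and marker blocks",
          class = "ngc_parameter_error")
  }
  role[free[1:10]] <- "sg2m"
  role[free[11:30]] <- "nes"
  role[free[31:50]] <- "dcx"
  role[free[51:200]] <- "wave"
  with_seed(substream_seed(config$seed, "embryonic"), {
    base <- model$base
    base[role == "sg2m"] <- base[role == "sg2m"] + 1.5  # cycling program
    # sequential waves: each wave gene switches on or off around its own
    # midpoint, spreading cells along a one-dimensional manifold
    n_wave <- sum(role == "wave")
    wave_mid <- runif(n_wave)
    wave_dir <- sample(c(-1, 1), n_wave, replace = TRUE)
    t <- runif(n_cells)
    cls <- if (n_classes > 0) sample(classes, n_cells, replace = TRUE) else NULL
    log_rel <- vapply(seq_len(n_cells), function(i) {
      lp <- base
      # logistic decay completing at t_star: expression is ~0 for t > t_star
      lp[role == "sg2m"] <- lp[role == "sg2m"] +
        log(plogis((t_star - 0.08 - t[i]) / 0.02) + 1e-8)
      lp[role == "nes"] <- lp[role == "nes"] - 2.5 * t[i]
      lp[role == "dcx"] <- lp[role == "dcx"] + 2.5 * (t[i] - 1)
      lp[role == "wave"] <- lp[role == "wave"] +
        3 * wave_dir * (plogis((t[i] - wave_mid) / 0.15) - 0.5)
      if (n_classes > 0) {
        lp[role == paste0("marker_", cls[i])] <-
          lp[role == paste0("marker_", cls[i])] + config$marker_log_fc
      }
      lp
    }, numeric(config$n_genes))
    colnames(log_rel) <- sprintf("emb_%04d", seq_len(n_cells))
    rownames(log_rel) <- model$ids
    counts <- sample_counts(log_rel, config)
    cells <- tibble(cell_id = colnames(counts),
                    true_maturation = t,
                    age = "E14.5",
                    platform = "embryonic_c1",
                    n_genes = full_scale_genes(counts, config$n_genes),
                    n_umis = full_depth_umis(n_cells),
                    n_reads = full_depth_umis(n_cells) * 3L,
                    mito_fraction = stats::rbeta(n_cells, 2, 38))
    if (n_classes > 0) cells$true_class <- cls
    ngc_counts(counts, cells, tibble(gene_id = model$ids, role = role,
                                     t_star = t_star))
  })
}
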