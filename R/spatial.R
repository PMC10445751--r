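# Landmark-normalized position analysis: KS tests, density profiles, layer
# fractions.

#' Normalize raw cell positions to a reference landmark
#'
#' Depth is the distance from the landmark (pia surface or ventricle) along
#' the normalization axis, zero at the landmark. The orthogonal axis is
#' replaced by seeded uniform jitter within the region limits — a display
#' coordinate only, flagged as such; depths are unaffected by the jitter.
#'
#' @param raw Tibble with `x_raw`, `y_raw`, `landmark` (per-cell landmark
#'   coordinate) and any grouping columns.
#' @param region_limits Length-2 numeric bounds of the jittered axis.
#' @param axis Normalization axis: depth is measured along `"y"` (default)
#'   or `"x"`.
#' @param jitter_seed Seed for the jitter.
#' @return Input tibble plus `depth` and `display_jitter` columns; cells
#'   whose depth exceeds the region extent are kept with a warning.
#' @export
normalize_positions <- function(raw, region_limits = c(0, 1000),
                                axis = c("y", "x"), jitter_seed = 1L) {
  axis <- match.arg(axis)
  coord <- if (axis == "y") raw$y_raw else raw$x_raw
  depth <- abs(coord - raw$landmark)
  if (any(depth > diff(range(region_limits)))) {
    warn("Cell(s) fall outside the region limits; kept.")
  }
  jit <- with_seed(substream_seed(jitter_seed, "position-jitter"),
                   runif(nrow(raw), region_limits[1], region_limits[2]))
  raw %>% mutate(depth = depth, display_jitter = jit)
}

#' Two-sided Kolmogorov-Smirnov comparison of depth samples
#'
#' D is the supremum absolute difference between the two empirical CDFs.
#' The exact p-value is used when `n_a * n_b <= 1e4` (and there are no
#' ties), the asymptotic approximation otherwise.
#'
#' @param depths_a,depths_b Numeric samples.
#' @return Tibble (`D`, `p`, `n_a`, `n_b`, `exact`).
#' @export
ks_compare <- function(depths_a, depths_b) {
  if (length(depths_a) < 1 || length(depths_b) < 1) {
    abort("Both samples must be non-empty.")
  }
  exact <- length(depths_a) * length(depths_b) <= 1e4
  kt <- suppressWarnings(ks.test(depths_a, depths_b, exact = exact))
  tibble(D = unname(kt$statistic), p = kt$p.value,
         n_a = length(depths_a), n_b = length(depths_b), exact = exact)
}

#' Gaussian kernel density profile over depth
#'
#' Kernel density estimate on a grid covering \[0, max depth\],
#' renormalized so the trapezoidal integral over the grid is 1.
#'
#' @param depths Numeric depths (>= 2 values).
#' @param bandwidth Numeric bandwidth or `"auto"` (Silverman's rule).
#' @param n_grid Grid size (default 512).
#' @return Tibble (`depth`, `density`).
#' @export
density_profile <- function(depths, bandwidth = "auto", n_grid = 512) {
  if (length(depths) < 2) abort("Need at least 2 points.")
  bw <- if (identical(bandwidth, "auto")) {
    if (sd(depths) == 0) {
      warn("Zero-variance input; using a delta-like narrow kernel.")
      max(1e-6, abs(mean(depths)) * 1e-3 + 1e-6)
    } else bw.nrd0(depths)
  } else bandwidth
  d <- density(depths, bw = bw, from = 0, to = max(depths), n = n_grid)
  dx <- diff(d$x)
  integral <- sum((d$y[-1] + d$y[-length(d$y)]) / 2 * dx)
  tibble(depth = d$x, density = d$y / integral)
}

#' Layer occupancy fractions per marker flag
#'
#' Half-open binning `[b_i, b_{i+1})` of depths into layers; depths beyond
#' the last boundary fall into an overflow bin. Percentages are computed
#' within each flag group.
#'
#' @param depths Numeric depths.
#' @param boundaries Strictly increasing layer boundaries.
#' @param flags Logical vector, or a data frame / named list of logical
#'   vectors (one column per marker).
#' @return Tibble (`flag`, `layer`, `n`, `pct`).
#' @export
layer_fractions <- function(depths, boundaries, flags) {
  if (is.unsorted(boundaries, strictly = TRUE)) {
    abort("`boundaries` must be strictly increasing.")
  }
  if (is.logical(flags)) flags <- list(flagged = flags)
  labs <- c(paste0("[", head(boundaries, -1), ",", boundaries[-1], ")"),
            paste0(">=", tail(boundaries, 1)))
  layer <- cut(depths, breaks = c(boundaries, Inf), right = FALSE,
               labels = labs)
  purrr::imap(as.list(flags), function(fl, nm) {
    sel <- layer[fl]
    tab <- table(sel)
    tibble(flag = nm, layer = names(tab), n = as.integer(tab),
           pct = 100 * as.integer(tab) / sum(tab))
  }) %>% dplyr::bind_rows()
}
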