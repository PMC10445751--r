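# Shared numerical helpers: seeding, normalization, variable genes.

#' Derive a deterministic substream seed
#'
#' All randomness in the package flows from one root seed; each generator or
#' pipeline stage draws from its own substream so that adding a stage never
#' perturbs the draws of another. The substream seed is the root seed combined
#' with a small polynomial hash of the stream name, reduced modulo 2^31 - 1 so
#' it stays a valid R integer.
#'
#' @param seed Integer root seed.
#' @param stream Character scalar naming the consumer (e.g. `"atlas"`).
#' @return An integer seed.
#' @export
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  # the seed initializes the hash state so that nearby seeds do not collide
  # with nearby stream names
  h <- abs(seed) %% 2147483647
  for (ch in utf8ToInt(stream)) h <- (h * 131 + ch) %% 2147483647
  as.integer(h)
}

# Evaluate `expr` under a local RNG state; restores .Random.seed afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Log-normalize a count matrix
#'
#' Scales each cell to a fixed library size and applies `log1p`. With
#' `scale = 1e6` this is the log1p-RPM transform used for fold changes and
#' signature scoring.
#'
#' @param counts Gene x cell matrix (sparse or dense) of non-negative counts.
#' @param scale Target library size (default 1e6, i.e. RPM).
#' @return Dense gene x cell matrix of log-normalized values.
#' @export
log_normalize <- function(counts, scale = 1e6) {
  m <- as.matrix(counts)
  libs <- colSums(m)
  libs[libs == 0] <- 1
  log1p(sweep(m, 2, libs, "/") * scale)
}

#' Rank variable genes by standardized dispersion
#'
#' Dispersion (variance/mean) of log-normalized expression, z-scored within
#' bins of similar mean expression, then ranked. This mirrors the common
#' mean-binned dispersion ranking used for variable-gene selection in
#' single-cell pipelines.
#'
#' @param lognorm Gene x cell matrix of log-normalized expression.
#' @param n Number of genes to return.
#' @param n_bins Number of mean-expression bins (default 20).
#' @return Character vector of gene names, most variable first.
#' @export
variable_genes <- function(lognorm, n = 2000, n_bins = 20) {
  mu <- rowMeans(lognorm)
  v <- apply(lognorm, 1, var)
  disp <- ifelse(mu > 0, v / mu, 0)
  bins <- cut(rank(mu, ties.method = "first"), breaks = n_bins, labels = FALSE)
  z <- disp
  for (b in unique(bins)) {
    i <- bins == b
    s <- sd(disp[i])
    z[i] <- if (is.na(s) || s == 0) 0 else (disp[i] - mean(disp[i])) / s
  }
  names(sort(z, decreasing = TRUE))[seq_len(min(n, length(z)))]
}

#' Residualize a matrix against a per-cell covariate
#'
#' Ordinary least squares of each gene on the covariate; returns residuals
#' with gene means restored. Used to regress out cell age before signature
#' selection and to remove sequencing-depth bias (number of genes expressed)
#' before trajectory reconstruction.
#'
#' @param mat Gene x cell numeric matrix.
#' @param covariate Numeric vector, one value per cell.
#' @return Matrix of the same shape.
#' @export
regress_out_covariate <- function(mat, covariate) {
  mat <- as.matrix(mat)
  if (length(covariate) != ncol(mat)) {
    abort("`covariate` must have one value per cell (column).")
  }
  cc <- covariate - mean(covariate)
  ss <- sum(cc^2)
  if (ss < .Machine$double.eps) {
    warn("Constant covariate: nothing to regress out; returning input.")
    return(mat)
  }
  mu <- rowMeans(mat)
  centered <- mat - mu
  beta <- as.vector(centered %*% cc) / ss
  centered - outer(beta, cc) + mu
}

# Nearest-rank upper-tail threshold: smallest value such that at least
# ceiling(n * (1 - p/100)) observations are >= it.
upper_nearest_rank <- function(x, percentile) {
  n <- length(x)
  k <- max(1L, ceiling(n * (1 - percentile / 100)))
  sort(x, decreasing = TRUE)[k]
}

`%theni%` <- function(a, b) if (length(a) == 0 || is.na(a[1])) b else a
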