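# Ordinal-regression maturation scoring: an L2-penalized cumulative-logit
# (proportional-odds) model over per-timepoint variable genes, cross-
# validated over the penalty grid. The contract is the continuum ordering of
# cells, not the coefficients of any particular solver.

# Negative log-likelihood and analytic gradient of the proportional-odds
# model. Parameters: beta (p), theta_1, log-increments of the remaining
# thresholds (keeps thresholds strictly increasing).
po_unpack <- function(par, p, K) {
  beta <- par[seq_len(p)]
  t1 <- par[p + 1]
  theta <- if (K > 2) cumsum(c(t1, exp(par[(p + 2):(p + K - 1)]))) else t1
  list(beta = beta, theta = theta)
}

po_nll <- function(par, X, y, K, lambda) {
  u <- po_unpack(par, ncol(X), K)
  eta <- drop(X %*% u$beta)
  th <- c(-Inf, u$theta, Inf)
  pk <- plogis(th[y + 1] - eta) - plogis(th[y] - eta)
  -sum(log(pmax(pk, 1e-12))) + lambda * sum(u$beta^2)
}

po_grad <- function(par, X, y, K, lambda) {
  p <- ncol(X)
  u <- po_unpack(par, p, K)
  eta <- drop(X %*% u$beta)
  th <- c(-Inf, u$theta, Inf)
  a <- th[y + 1] - eta   # upper cut
  b <- th[y] - eta       # lower cut
  Fa <- plogis(a); Fb <- plogis(b)
  fa <- Fa * (1 - Fa); fb <- Fb * (1 - Fb)
  pk <- pmax(Fa - Fb, 1e-12)
  # d nll / d eta
  deta <- (fa - fb) / pk
  gbeta <- drop(crossprod(X, deta)) + 2 * lambda * u$beta
  # d nll / d theta_j : theta_j appears as upper cut for y == j, lower for y == j+1
  gtheta <- numeric(K - 1)
  for (j in seq_len(K - 1)) {
    up <- y == j
    lo <- y == j + 1
    gtheta[j] <- -sum(fa[up] / pk[up]) + sum(fb[lo] / pk[lo])
  }
  # chain rule through the log-increment parameterization
  gt1 <- sum(gtheta)
  out <- c(gbeta, gt1)
  if (K > 2) {
    inc <- exp(par[(p + 2):(p + K - 1)])
    gout <- vapply(seq_len(K - 2), function(m) {
      sum(gtheta[(m + 1):(K - 1)]) * inc[m]
    }, numeric(1))
    out <- c(out, gout)
  }
  out
}

fit_po <- function(X, y, K, lambda) {
  p <- ncol(X)
  start <- c(numeric(p), seq(-1, 1, length.out = K - 1))
  if (K > 2) {
    start <- c(numeric(p), -1, log(diff(seq(-1, 1, length.out = K - 1))))
  }
  opt <- optim(start, po_nll, po_grad, X = X, y = y, K = K, lambda = lambda,
               method = "BFGS", control = list(maxit = 300))
  po_unpack(opt$par, p, K)
}

po_predict_class <- function(fit, X, K) {
  eta <- drop(X %*% fit$beta)
  th <- c(-Inf, fit$theta, Inf)
  probs <- vapply(seq_len(K), function(k) {
    plogis(th[k + 1] - eta) - plogis(th[k] - eta)
  }, numeric(nrow(X)))
  max.col(probs, ties.method = "first")
}

#' Fit a regularized ordinal maturation model
#'
#' Orders cells on a continuous maturation score: a cumulative-logit
#' (proportional-odds) linear model with an L2 penalty is trained on the
#' union of per-timepoint variable genes; k-fold cross-validation selects
#' the penalty; the linear predictor is the maturation score.
#'
#' @param expr `ngc_counts` or log-normalized gene x cell matrix.
#' @param timepoints Named (by cell id) or positional vector of timepoint
#'   labels, in developmental order given by `levels` (or order of first
#'   appearance).
#' @param levels Ordered timepoint labels (default `unique(timepoints)`).
#' @param folds Cross-validation folds (default 10).
#' @param n_var_genes Variable genes selected per timepoint (default 50).
#' @param lambda_grid L2 penalties tried (default `10^seq(-2, 2)`).
#' @param seed Seed for fold assignment.
#' @return An `ngc_maturation` model with `genes`, `center`, `scale`,
#'   `beta`, `theta`, `lambda`, `cv` (accuracy per lambda), `levels`.
#' @export
fit_maturation_order <- function(expr, timepoints, levels = NULL, folds = 10,
                                 n_var_genes = 50,
                                 lambda_grid = 10^seq(-2, 2), seed = 1L) {
  mat <- if (inherits(expr, "ngc_counts")) log_rpm(expr) else as.matrix(expr)
  tp <- if (!is.null(names(timepoints))) unname(timepoints[colnames(mat)])
        else timepoints
  if (is.null(levels)) levels <- unique(tp)
  if (length(levels) < 2) abort("Need at least two timepoints.")
  y <- match(tp, levels)
  if (anyNA(y)) abort("Timepoint labels outside `levels`.")
  if (any(table(y) < folds)) {
    abort("Each timepoint needs at least `folds` cells.")
  }
  gene_set <- unique(unlist(lapply(levels, function(l) {
    variable_genes(mat[, y == match(l, levels), drop = FALSE], n_var_genes)
  })))
  X <- t(mat[gene_set, , drop = FALSE])
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd); scl[scl == 0] <- 1
  Xs <- scale(X, ctr, scl)
  K <- length(levels)
  fold_id <- with_seed(substream_seed(seed, "maturation-cv"), {
    unlist(tapply(seq_along(y), y, function(i) {
      sample(rep_len(seq_len(folds), length(i)))
    }))[order(unlist(tapply(seq_along(y), y, identity)))]
  })
  cv <- map_dbl(lambda_grid, function(lam) {
    acc <- map_dbl(seq_len(folds), function(f) {
      tr <- fold_id != f
      if (length(unique(y[tr])) < K) return(NA_real_)
      fit <- fit_po(Xs[tr, , drop = FALSE], y[tr], K, lam)
      mean(po_predict_class(fit, Xs[!tr, , drop = FALSE], K) == y[!tr])
    })
    mean(acc, na.rm = TRUE)
  })
  lambda <- lambda_grid[which.max(cv)]
  fit <- fit_po(Xs, y, K, lambda)
  structure(list(genes = gene_set, center = ctr, scale = scl,
                 beta = fit$beta, theta = fit$theta, lambda = lambda,
                 cv = tibble(lambda = lambda_grid, accuracy = cv),
                 levels = levels, folds = folds),
            class = "ngc_maturation")
}

#' Score cells on a fitted maturation model
#'
#' Returns the linear predictor of the proportional-odds model as the
#' continuous maturation score. Model genes missing from the input are
#' imputed at the training mean (zero after standardization) with a
#' warning.
#'
#' @param model An `ngc_maturation` from [fit_maturation_order()].
#' @param cells `ngc_counts` or log-normalized gene x cell matrix.
#' @return Tibble (`cell_id`, `maturation_score`).
#' @export
score_maturation <- function(model, cells) {
  mat <- if (inherits(cells, "ngc_counts")) log_rpm(cells) else as.matrix(cells)
  present <- intersect(model$genes, rownames(mat))
  if (length(present) == 0) abort("No model genes present in the input.")
  if (length(present) < length(model$genes)) {
    warn(sprintf("%d of %d model genes missing; imputing at training mean.",
                 length(model$genes) - length(present), length(model$genes)))
  }
  X <- matrix(0, ncol(mat), length(model$genes),
              dimnames = list(colnames(mat), model$genes))
  X[, present] <- t(mat[present, , drop = FALSE])
  missing <- setdiff(model$genes, present)
  if (length(missing)) X[, missing] <- rep(model$center[missing], each = nrow(X))
  Xs <- scale(X, model$center, model$scale)
  tibble(cell_id = colnames(mat),
         maturation_score = unname(drop(Xs %*% model$beta)))
}

#' @export
print.ngc_maturation <- function(x, ...) {
  cat(sprintf("<ngc_maturation> %d timepoints (%s), %d genes, lambda=%g\n",
              length(x$levels), paste(x$levels, collapse = " < "),
              length(x$genes), x$lambda))
  invisible(x)
}

#' @export
tidy.ngc_maturation <- function(x, ...) {
  tibble(gene = x$genes, weight = x$beta)
}

#' @export
glance.ngc_maturation <- function(x, ...) {
  tibble(n_timepoints = length(x$levels), n_genes = length(x$genes),
         lambda = x$lambda, cv_accuracy = max(x$cv$accuracy), folds = x$folds)
}
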