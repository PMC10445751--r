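# Hastie-Stuetzle principal curve: alternate projection onto the current
# curve and per-coordinate smoothing against arc length.

# Project points (n x d) onto the polyline with vertices V (m x d).
# Returns per-point arc length, squared distance and the projected point.
project_to_polyline <- function(P, V) {
  n <- nrow(P); m <- nrow(V)
  if (m < 2) abort("Polyline needs at least two vertices.")
  seg_len <- sqrt(rowSums((V[-1, , drop = FALSE] - V[-m, , drop = FALSE])^2))
  cum0 <- c(0, cumsum(seg_len))
  best_d2 <- rep(Inf, n)
  best_lambda <- numeric(n)
  best_pt <- matrix(0, n, ncol(P))
  for (s in seq_len(m - 1)) {
    A <- V[s, ]; B <- V[s + 1, ]
    AB <- B - A
    len2 <- sum(AB^2)
    t <- if (len2 == 0) rep(0, n)
         else pmin(1, pmax(0, (sweep(P, 2, A) %*% AB) / len2))
    proj <- outer(drop(t), AB) + matrix(A, n, ncol(P), byrow = TRUE)
    d2 <- rowSums((P - proj)^2)
    upd <- d2 < best_d2
    best_d2[upd] <- d2[upd]
    best_lambda[upd] <- cum0[s] + drop(t)[upd] * seg_len[s]
    best_pt[upd, ] <- proj[upd, , drop = FALSE]
  }
  list(lambda = best_lambda, d2 = best_d2, proj = best_pt)
}

#' Fit a principal curve
#'
#' Hastie-Stuetzle iteration: initialize with the first principal component,
#' then alternate (i) projecting points onto the current curve to obtain arc
#' lengths and (ii) smoothing each coordinate against arc length with a
#' cubic smoothing spline, until the mean squared projection distance
#' changes by less than `tol` (relative) or `max_iter` is reached.
#'
#' @param points Numeric matrix (cells x dims), e.g. kept PCs from
#'   [pca_keep()].
#' @param max_iter Maximum iterations (default 50).
#' @param tol Relative convergence tolerance on the mean squared projection
#'   distance (default 1e-4).
#' @return An `ngc_principal_curve`: `curve` (ordered vertex matrix),
#'   `lambda` (per-cell arc length), `proj` (projected points), `d2_trace`
#'   (mean squared distance per iteration), `converged`.
#' @export
fit_principal_curve <- function(points, max_iter = 50, tol = 1e-4) {
  P <- as.matrix(points)
  if (nrow(P) < 10) abort("Need at least 10 points.")
  d <- ncol(P)
  # collapse exact duplicates into weighted unique points so the smoother
  # sees the empirical distribution, not the multiplicity
  key <- apply(P, 1, paste, collapse = ",")
  uniq <- !duplicated(key)
  U <- P[uniq, , drop = FALSE]
  w_u <- as.vector(table(factor(key, levels = key[uniq])))
  back <- match(key, key[uniq])
  ctr <- colSums(U * w_u) / sum(w_u)
  Uc <- sweep(U, 2, ctr)
  v1 <- svd(Uc * sqrt(w_u), nu = 0, nv = 1)$v[, 1]
  lambda <- drop(Uc %*% v1)
  ord <- order(lambda)
  curve <- sweep(outer(lambda[ord], v1), 2, ctr, `+`)
  pr <- project_to_polyline(U, curve)
  d2 <- sum(pr$d2 * w_u) / sum(w_u)
  d2_trace <- d2
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    lambda <- pr$lambda
    ord <- order(lambda)
    lam_s <- lambda[ord]
    if (length(unique(lam_s)) < 4) break
    fitted_curve <- vapply(seq_len(d), function(j) {
      sp <- smooth.spline(lam_s, U[ord, j], w = w_u[ord])
      predict(sp, lam_s)$y
    }, numeric(length(lam_s)))
    pr_new <- project_to_polyline(U, fitted_curve)
    d2_new <- sum(pr_new$d2 * w_u) / sum(w_u)
    d2_trace <- c(d2_trace, d2_new)
    pr <- pr_new
    curve <- fitted_curve
    if (d2 < .Machine$double.eps ||
        abs(d2 - d2_new) / max(d2, .Machine$double.eps) < tol) {
      converged <- TRUE
      d2 <- d2_new
      break
    }
    d2 <- d2_new
  }
  structure(list(curve = curve, lambda = pr$lambda[back],
                 proj = pr$proj[back, , drop = FALSE],
                 d2_trace = d2_trace, converged = converged),
            class = "ngc_principal_curve")
}

#' @export
print.ngc_principal_curve <- function(x, ...) {
  cat(sprintf("<ngc_principal_curve> %d vertices, mean sq. distance %.4g, %s\n",
              nrow(x$curve), tail(x$d2_trace, 1),
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}
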