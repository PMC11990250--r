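#' Linear canonical correlation analysis
#'
#' Fits projection weight matrices `u` (p x k) and `v` (q x k) that
#' maximize the Pearson correlation between successive pairs of
#' canonical variates `Xu`, `Yv`, subject to unit-variance and
#' within-view orthogonality constraints. Solved as the SVD of the
#' whitened cross-covariance `(Sx + ridge I)^(-1/2) Sxy (Sy + ridge I)^(-1/2)`.
#' Weights are rescaled so each training variate has exactly unit sample
#' variance, and signs are fixed so that `cor(Xu_j, Yv_j) >= 0` and the
#' largest-magnitude entry of `u_j` is positive.
#'
#' @param X,Y row-aligned numeric matrices (n x p, n x q).
#' @param k number of component pairs (default 20). `k <= min(p, q)`.
#' @param ridge nonnegative ridge added to each view's covariance
#'   diagonal; `NULL` (default) uses `0.02 * trace(S)/p` per view — 2%
#'   of the mean feature variance, enough to keep weakly-informative
#'   directions from dominating the whitening at `p` of order `n/20` —
#'   and `0` disables it (an explicit error is raised if a covariance is
#'   then numerically singular).
#' @return A `cca_model`: weights `u`, `v`; `train_correlations`
#'   (Pearson r of the training variates, nonincreasing); `singular_values`
#'   of the whitened cross-covariance; training column means `center_x`,
#'   `center_y`; `ridge` (per view); `train_n`.
#' @export
fit_cca <- function(X, Y, k = 20, ridge = NULL) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X); p <- ncol(X); q <- ncol(Y)
  if (nrow(Y) != n) stop("X and Y must have the same number of rows")
  if (k > min(p, q)) stop("k = ", k, " exceeds min(p, q) = ", min(p, q))
  if (n <= k) stop("need n > k")
  cx <- colMeans(X); cy <- colMeans(Y)
  Xc <- sweep(X, 2, cx); Yc <- sweep(Y, 2, cy)
  Sx <- crossprod(Xc) / (n - 1)
  Sy <- crossprod(Yc) / (n - 1)
  Sxy <- crossprod(Xc, Yc) / (n - 1)
  rx <- if (is.null(ridge)) 0.02 * sum(diag(Sx)) / p else ridge
  ry <- if (is.null(ridge)) 0.02 * sum(diag(Sy)) / q else ridge
  Wx <- inv_sqrt_sym(Sx, rx, "X")
  Wy <- inv_sqrt_sym(Sy, ry, "Y")
  sv <- svd(Wx %*% Sxy %*% Wy)
  u <- Wx %*% sv$u[, seq_len(k), drop = FALSE]
  v <- Wy %*% sv$v[, seq_len(k), drop = FALSE]
  # exact unit training-variate variance (undo the small ridge shrinkage)
  su <- sqrt(pmax(colSums((Sx %*% u) * u), .Machine$double.eps))
  sv2 <- sqrt(pmax(colSums((Sy %*% v) * v), .Machine$double.eps))
  u <- sweep(u, 2, su, `/`); v <- sweep(v, 2, sv2, `/`)
  vx <- Xc %*% u; vy <- Yc %*% v
  r <- diag(stats::cor(vx, vy))
  flip <- r < 0
  v[, flip] <- -v[, flip]; vy[, flip] <- -vy[, flip]; r <- abs(r)
  for (j in seq_len(k)) {
    i <- which.max(abs(u[, j]))
    if (u[i, j] < 0) {
      u[, j] <- -u[, j]; v[, j] <- -v[, j]
    }
  }
  structure(list(u = u, v = v, train_correlations = r,
                 singular_values = sv$d[seq_len(k)],
                 center_x = cx, center_y = cy,
                 ridge = c(x = rx, y = ry), train_n = n, k = as.integer(k)),
            class = "cca_model")
}

# symmetric inverse square root with ridge; errors on singularity at ridge 0
inv_sqrt_sym <- function(S, ridge, label) {
  eg <- eigen(S + diag(ridge, nrow(S)), symmetric = TRUE)
  tol <- max(eg$values) * 1e-12
  if (any(eg$values < tol))
    stop("covariance of view ", label, " is numerically singular; ",
         "supply a positive ridge (e.g. ridge = 1e-4 * mean variance)")
  eg$vectors %*% (t(eg$vectors) / sqrt(eg$values))
}

#' Project data through a fitted CCA model
#'
#' Centers with the training means, applies the stored weights, and
#' reports the per-component Pearson correlation on the supplied data.
#'
#' @param model a `cca_model`.
#' @param X,Y row-aligned matrices with the training column counts.
#' @return List with `variates_x`, `variates_y` (n x k) and
#'   `correlations` (length k).
#' @export
cca_project <- function(model, X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (ncol(X) != nrow(model$u) || ncol(Y) != nrow(model$v))
    stop("column counts do not match the fitted model")
  if (nrow(X) != nrow(Y)) stop("X and Y must have the same number of rows")
  vx <- sweep(X, 2, model$center_x) %*% model$u
  vy <- sweep(Y, 2, model$center_y) %*% model$v
  list(variates_x = vx, variates_y = vy,
       correlations = diag(stats::cor(vx, vy)))
}

#' Two-sided p-value of a Pearson correlation
#'
#' Uses the exact t transform `t = r sqrt(n - 2) / sqrt(1 - r^2)` on
#' `n - 2` degrees of freedom.
#'
#' @param r correlation(s) in \[-1, 1\].
#' @param n sample size (>= 3).
#' @return Two-sided p-value(s); `|r| = 1` returns 0 with a degeneracy
#'   warning.
#' @export
correlation_significance <- function(r, n) {
  if (n < 3) stop("need n >= 3")
  if (any(abs(r) > 1 + 1e-12)) stop("|r| must be <= 1")
  r <- pmin(pmax(r, -1), 1)
  p <- numeric(length(r))
  deg <- abs(r) >= 1
  if (any(deg)) {
    warning("|r| = 1 is degenerate; returning p = 0")
    p[deg] <- 0
  }
  t <- r[!deg] * sqrt(n - 2) / sqrt(1 - r[!deg]^2)
  p[!deg] <- 2 * stats::pt(-abs(t), df = n - 2)
  p
}

#' Dual-split significance screen of component correlations
#'
#' A component is flagged significant only when its correlation p-value
#' is below `alpha / m` in BOTH the training and the testing split.
#'
#' @param train_r,test_r per-component correlations on each split.
#' @param train_n,test_n split sizes.
#' @param alpha family-wise level (default 0.05).
#' @param m number of tests for the Bonferroni correction (default: the
#'   number of components).
#' @return A `component_screen` data frame with columns `component`,
#'   `train_r`, `train_p`, `test_r`, `test_p`, `significant`; attributes
#'   `alpha_corrected` and `m_tests`.
#' @export
select_significant <- function(train_r, test_r, train_n, test_n,
                               alpha = 0.05, m = length(train_r)) {
  if (length(train_r) != length(test_r))
    stop("train and test correlation vectors must have equal length")
  if (m < 1) stop("m must be >= 1")
  tp <- correlation_significance(train_r, train_n)
  sp <- correlation_significance(test_r, test_n)
  ac <- alpha / m
  out <- data.frame(component = seq_along(train_r),
                    train_r = train_r, train_p = tp,
                    test_r = test_r, test_p = sp,
                    significant = tp < ac & sp < ac)
  attr(out, "alpha_corrected") <- ac
  attr(out, "m_tests") <- as.integer(m)
  class(out) <- c("component_screen", "data.frame")
  out
}
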