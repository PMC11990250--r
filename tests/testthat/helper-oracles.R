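# Brute-force canonical-correlation oracle, computed along a different
# route than the package (Cholesky whitening instead of symmetric
# eigen-square-root): canonical correlations are invariant to the
# whitening factor chosen.
oracle_cca_correlations <- function(X, Y, k, ridge = 0) {
  n <- nrow(X)
  Xc <- scale(X, scale = FALSE); Yc <- scale(Y, scale = FALSE)
  Sx <- crossprod(Xc) / (n - 1) + diag(ridge, ncol(X))
  Sy <- crossprod(Yc) / (n - 1) + diag(ridge, ncol(Y))
  Sxy <- crossprod(Xc, Yc) / (n - 1)
  Lx <- chol(Sx); Ly <- chol(Sy)
  T <- t(solve(Lx, diag(ncol(X)))) %*% Sxy %*% solve(Ly, diag(ncol(Y)))
  svd(T)$d[seq_len(k)]
}

# small coupled dataset for quick model tests
tiny_views <- function(n = 400, p = 12, q = 10, rho = c(0.7, 0.4),
                       seed = 1, mixing = "linear") {
  spec <- synthetic_spec(n_subjects = n, p_x = p, p_y = q,
                         canonical_corrs = rho, mixing = mixing, seed = seed)
  generate_coupled_views(spec)
}
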