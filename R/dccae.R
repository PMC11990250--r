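#' Configuration of a deep CCA autoencoder
#'
#' Per-view encoders map inputs through tanh hidden layers to a linear
#' latent layer; decoders mirror the encoders. Training minimizes
#' `(1 - lambda_recon) * correlation loss + lambda_recon * (mse_x + mse_y)`
#' by plain minibatch gradient descent, where the correlation loss is
#' minus the sum of the top `k_corr` singular values of the whitened
#' cross-covariance of the two latent batches (ridges `r_x`, `r_y` on
#' the latent covariances).
#'
#' @param hidden integer vector of hidden-layer widths for the encoder
#'   (default 100, a single hidden layer); `integer(0)` gives a purely
#'   linear encoder (the ablated architecture).
#' @param latent latent width (default 20).
#' @param k_corr number of components in the correlation objective
#'   (default = `latent`); must be at most `latent` and smaller than
#'   `batch_size`.
#' @param lambda_recon reconstruction weight in \[0, 1\] (default 0.08;
#'   the correlation weight is `1 - lambda_recon` = 0.92).
#' @param r_x,r_y covariance ridges inside the correlation loss
#'   (default 0.1: minibatch covariances of a 20-dimensional latent at
#'   batch size 256 need substantial shrinkage for stable whitening;
#'   the hard unit-variance constraint is enforced afterwards by the
#'   post-hoc CCA, so this ridge only smooths the training signal).
#' @param lr learning rate (default 0.01).
#' @param momentum heavy-ball momentum coefficient of the minibatch
#'   gradient descent (default 0, plain SGD).
#' @param epochs training epochs (default 150).
#' @param batch_size minibatch size (default 256).
#' @param folds folds for [cross_validate()] (default 5).
#' @param seed integer seed controlling initialization and batching.
#' @return A `dccae_config` list.
#' @export
dccae_config <- function(hidden = 100L, latent = 20L, k_corr = latent,
                         lambda_recon = 0.08, r_x = 0.1, r_y = 0.1,
                         lr = 0.01, momentum = 0, epochs = 150L,
                         batch_size = 256L, folds = 5L, seed = 1L) {
  if (lambda_recon < 0 || lambda_recon > 1)
    stop("lambda_recon must lie in [0, 1]")
  if (k_corr > latent) stop("k_corr must be at most the latent width")
  if (batch_size <= k_corr)
    stop("batch_size must exceed k_corr for covariance estimability")
  structure(list(hidden = as.integer(hidden), latent = as.integer(latent),
                 k_corr = as.integer(k_corr), lambda_recon = lambda_recon,
                 r_x = r_x, r_y = r_y, lr = lr, momentum = momentum,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), folds = as.integer(folds),
                 seed = as.integer(seed)),
            class = "dccae_config")
}

#' Remove the hidden layers of an encoder configuration
#'
#' Returns a configuration whose encoder is a single affine map from
#' input to latent (no nonlinearity), with the decoder mirrored — the
#' linear ablation used to probe whether nonlinearity adds correlation
#' strength.
#'
#' @param config a `dccae_config` with at least one hidden layer.
#' @return The ablated `dccae_config`.
#' @export
ablate_linear <- function(config) {
  stopifnot(inherits(config, "dccae_config"))
  if (length(config$hidden) < 1)
    stop("config already has no hidden layer")
  config$hidden <- integer(0)
  config
}

#' Mean squared reconstruction error
#'
#' Mean over samples of the squared Euclidean row norm of `X - X_hat`
#' (per-sample mean convention: the feature dimension is summed, not
#' averaged).
#'
#' @param X,X_hat matrices of identical shape.
#' @return Scalar loss.
#' @export
reconstruction_loss <- function(X, X_hat) {
  if (!identical(dim(X), dim(X_hat))) stop("shape mismatch")
  sum((X - X_hat)^2) / nrow(X)
}

#' Canonical-correlation loss of two latent batches
#'
#' Returns minus the sum of the top-`k` singular values of
#' `T = (Cxx + r_x I)^(-1/2) Cxy (Cyy + r_y I)^(-1/2)`, with batch-centered
#' covariances scaled by `1/(n - 1)`. Minimizing it maximizes the total
#' canonical correlation of the batch.
#'
#' @param FX,GY n x d latent batches (n > d required).
#' @param k number of singular values summed (`k <= d`).
#' @param r_x,r_y nonnegative covariance ridges.
#' @param with_grad if `TRUE`, also return the gradients with respect to
#'   `FX` and `GY`.
#' @return The scalar loss, or (with `with_grad`) a list
#'   `(loss, grad_fx, grad_gy)`.
#' @export
cca_loss <- function(FX, GY, k = ncol(FX), r_x = 1e-3, r_y = 1e-3,
                     with_grad = FALSE) {
  n <- nrow(FX); d1 <- ncol(FX); d2 <- ncol(GY)
  if (nrow(GY) != n) stop("batches must have equal row counts")
  if (n <= max(d1, d2))
    stop("batch size (", n, ") must exceed the latent width; use a larger batch")
  if (k > min(d1, d2)) stop("k exceeds the latent width")
  A <- scale(FX, scale = FALSE); B <- scale(GY, scale = FALSE)
  if (!all(is.finite(A)) || !all(is.finite(B)))
    stop("non-finite latent values; training diverged")
  S11 <- crossprod(A) / (n - 1) + diag(r_x, d1)
  S22 <- crossprod(B) / (n - 1) + diag(r_y, d2)
  S12 <- crossprod(A, B) / (n - 1)
  W1 <- inv_sqrt_sym(S11, 0, "latent X")
  W2 <- inv_sqrt_sym(S22, 0, "latent Y")
  sv <- svd(W1 %*% S12 %*% W2)
  loss <- -sum(sv$d[seq_len(k)])
  if (!with_grad) return(loss)
  U <- sv$u[, seq_len(k), drop = FALSE]
  V <- sv$v[, seq_len(k), drop = FALSE]
  D <- sv$d[seq_len(k)]
  D11 <- -0.5 * W1 %*% (U %*% (D * t(U))) %*% W1
  D22 <- -0.5 * W2 %*% (V %*% (D * t(V))) %*% W2
  D12 <- W1 %*% U %*% t(V) %*% W2
  # gradient of +sum(top-k singular values) wrt the centered batches
  g_fx <- (2 * A %*% D11 + B %*% t(D12)) / (n - 1)
  g_gy <- (2 * B %*% D22 + A %*% D12) / (n - 1)
  # chain through centering, then negate for the loss
  g_fx <- -sweep(g_fx, 2, colMeans(g_fx))
  g_gy <- -sweep(g_gy, 2, colMeans(g_gy))
  list(loss = loss, grad_fx = g_fx, grad_gy = g_gy)
}

# ---- minimal MLP machinery (tanh hiddens, linear output) ----

mlp_init <- function(widths) {
  L <- length(widths) - 1
  lapply(seq_len(L), function(l) {
    fan_in <- widths[l]; fan_out <- widths[l + 1]
    s <- sqrt(6 / (fan_in + fan_out))
    list(W = matrix(stats::runif(fan_in * fan_out, -s, s), fan_in, fan_out),
         b = numeric(fan_out))
  })
}

# returns list(out, cache) ; tanh on all but the last layer
mlp_forward <- function(params, X) {
  L <- length(params)
  acts <- vector("list", L + 1)
  acts[[1]] <- X
  for (l in seq_len(L)) {
    z <- sweep(acts[[l]] %*% params[[l]]$W, 2, params[[l]]$b, `+`)
    acts[[l + 1]] <- if (l < L) tanh(z) else z
  }
  list(out = acts[[L + 1]], acts = acts)
}

# grad_out: dLoss/dOutput; returns list(grads = per-layer (W, b), grad_in)
mlp_backward <- function(params, cache, grad_out) {
  L <- length(params)
  grads <- vector("list", L)
  delta <- grad_out
  for (l in rev(seq_len(L))) {
    a_in <- cache$acts[[l]]
    grads[[l]] <- list(W = crossprod(a_in, delta), b = colSums(delta))
    if (l > 1) {
      delta <- delta %*% t(params[[l]]$W)
      delta <- delta * (1 - cache$acts[[l]]^2)  # tanh'
    }
  }
  list(grads = grads, grad_in = NULL)
}

mlp_step <- function(params, grads, lr, vel, momentum) {
  for (l in seq_along(params)) {
    vel[[l]]$W <- momentum * vel[[l]]$W + grads[[l]]$W
    vel[[l]]$b <- momentum * vel[[l]]$b + grads[[l]]$b
    params[[l]]$W <- params[[l]]$W - lr * vel[[l]]$W
    params[[l]]$b <- params[[l]]$b - lr * vel[[l]]$b
  }
  list(params = params, vel = vel)
}

mlp_zero_vel <- function(params) {
  lapply(params, function(l) list(W = 0 * l$W, b = 0 * l$b))
}

# gradient at the input of a network given grad at its output
mlp_input_grad <- function(params, cache, grad_out) {
  L <- length(params)
  delta <- grad_out
  for (l in rev(seq_len(L))) {
    if (l < L) delta <- delta * (1 - cache$acts[[l + 1]]^2)
    delta <- delta %*% t(params[[l]]$W)
  }
  delta
}

#' Train a deep CCA autoencoder
#'
#' Minimizes `(1 - lambda) * cca_loss(f(X), g(Y)) +
#' lambda * (recon_x + recon_y)` over minibatches with plain gradient
#' descent, then fits a linear CCA ([fit_cca()]) on the full-training
#' encodings to obtain the post-hoc canonical weights used for
#' projection and screening. Deterministic given `config$seed`.
#'
#' @param X,Y row-aligned training matrices.
#' @param config a [dccae_config()].
#' @return A `dccae_model`: encoder/decoder parameter lists per view,
#'   the post-hoc `cca` (a `cca_model`), the `config`, and the per-epoch
#'   `loss_trace` (columns `total`, `corr`, `recon`).
#' @export
train_dccae <- function(X, Y, config) {
  stopifnot(inherits(config, "dccae_config"))
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  if (nrow(Y) != n) stop("X and Y must have the same number of rows")
  set.seed(config$seed)
  wx <- c(ncol(X), config$hidden, config$latent)
  wy <- c(ncol(Y), config$hidden, config$latent)
  enc_x <- mlp_init(wx); dec_x <- mlp_init(rev(wx))
  enc_y <- mlp_init(wy); dec_y <- mlp_init(rev(wy))
  v_ex <- mlp_zero_vel(enc_x); v_ey <- mlp_zero_vel(enc_y)
  v_dx <- mlp_zero_vel(dec_x); v_dy <- mlp_zero_vel(dec_y)
  lam <- config$lambda_recon
  bs <- min(config$batch_size, n)
  if (bs <= config$latent)
    stop("batch size must exceed the latent width")
  trace <- matrix(NA_real_, config$epochs, 3,
                  dimnames = list(NULL, c("total", "corr", "recon")))
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    ep_tot <- ep_corr <- ep_rec <- 0; nb <- 0
    for (start in seq(1, n, by = bs)) {
      idx <- ord[start:min(start + bs - 1, n)]
      if (length(idx) <= config$latent) next  # ragged tail too small
      xb <- X[idx, , drop = FALSE]; yb <- Y[idx, , drop = FALSE]
      fe <- mlp_forward(enc_x, xb); ge <- mlp_forward(enc_y, yb)
      fd <- mlp_forward(dec_x, fe$out); gd <- mlp_forward(dec_y, ge$out)
      cl <- cca_loss(fe$out, ge$out, config$k_corr, config$r_x, config$r_y,
                     with_grad = TRUE)
      rl_x <- reconstruction_loss(xb, fd$out)
      rl_y <- reconstruction_loss(yb, gd$out)
      total <- (1 - lam) * cl$loss + lam * (rl_x + rl_y)
      if (!is.finite(total))
        stop("training diverged (non-finite loss) at epoch ", ep,
             "; loss trace so far: ",
             paste(round(stats::na.omit(trace[, "total"]), 3), collapse = " "))
      m <- length(idx)
      g_rec_x <- lam * 2 * (fd$out - xb) / m
      g_rec_y <- lam * 2 * (gd$out - yb) / m
      bd_x <- mlp_backward(dec_x, fd, g_rec_x)
      bd_y <- mlp_backward(dec_y, gd, g_rec_y)
      g_lat_x <- (1 - lam) * cl$grad_fx + mlp_input_grad(dec_x, fd, g_rec_x)
      g_lat_y <- (1 - lam) * cl$grad_gy + mlp_input_grad(dec_y, gd, g_rec_y)
      be_x <- mlp_backward(enc_x, fe, g_lat_x)
      be_y <- mlp_backward(enc_y, ge, g_lat_y)
      s1 <- mlp_step(enc_x, be_x$grads, config$lr, v_ex, config$momentum)
      enc_x <- s1$params; v_ex <- s1$vel
      s2 <- mlp_step(enc_y, be_y$grads, config$lr, v_ey, config$momentum)
      enc_y <- s2$params; v_ey <- s2$vel
      s3 <- mlp_step(dec_x, bd_x$grads, config$lr, v_dx, config$momentum)
      dec_x <- s3$params; v_dx <- s3$vel
      s4 <- mlp_step(dec_y, bd_y$grads, config$lr, v_dy, config$momentum)
      dec_y <- s4$params; v_dy <- s4$vel
      ep_tot <- ep_tot + total; ep_corr <- ep_corr + cl$loss
      ep_rec <- ep_rec + rl_x + rl_y; nb <- nb + 1
    }
    trace[ep, ] <- c(ep_tot, ep_corr, ep_rec) / nb
  }
  FX <- mlp_forward(enc_x, X)$out
  GY <- mlp_forward(enc_y, Y)$out
  cca <- fit_cca(FX, GY, k = config$k_corr)
  structure(list(enc_x = enc_x, enc_y = enc_y, dec_x = dec_x, dec_y = dec_y,
                 cca = cca, config = config, loss_trace = trace),
            class = "dccae_model")
}

#' Encode one view with a trained model
#' @param model a `dccae_model`.
#' @param X input matrix.
#' @param view `"X"` or `"Y"`.
#' @return n x latent encoding matrix.
#' @export
dccae_encode <- function(model, X, view = c("X", "Y")) {
  view <- match.arg(view)
  enc <- if (view == "X") model$enc_x else model$enc_y
  mlp_forward(enc, as.matrix(X))$out
}

#' Project data through a trained DCCAE and screen components
#'
#' Encodes both views, applies the stored post-hoc canonical weights and
#' returns the per-component correlations. When a test split is also
#' supplied, the dual-split Bonferroni screen is computed.
#'
#' @param model a fitted `dccae_model`.
#' @param X,Y row-aligned data for the two views.
#' @param X_test,Y_test optional held-out split for the screen.
#' @param alpha family-wise level (default 0.05).
#' @param m number of tests for Bonferroni (default: number of components).
#' @return List with `variates_x`, `variates_y`, `correlations`, and —
#'   when a test split is given — `test_variates_x`, `test_variates_y`,
#'   `test_correlations` and `screen` (a `component_screen`).
#' @export
encode_and_cca <- function(model, X, Y, X_test = NULL, Y_test = NULL,
                           alpha = 0.05, m = model$config$k_corr) {
  stopifnot(inherits(model, "dccae_model"))
  pr <- cca_project(model$cca, dccae_encode(model, X, "X"),
                    dccae_encode(model, Y, "Y"))
  out <- list(variates_x = pr$variates_x, variates_y = pr$variates_y,
              correlations = pr$correlations)
  if (!is.null(X_test)) {
    pt <- cca_project(model$cca, dccae_encode(model, X_test, "X"),
                      dccae_encode(model, Y_test, "Y"))
    out$test_variates_x <- pt$variates_x
    out$test_variates_y <- pt$variates_y
    out$test_correlations <- pt$correlations
    out$screen <- select_significant(pr$correlations, pt$correlations,
                                     nrow(X), nrow(X_test), alpha, m)
  }
  out
}

#' Cross-validated hyperparameter selection
#'
#' For each candidate configuration, trains on each of `folds - 1` fold
#' complements and scores the held-out fold by the sum of its first 10
#' canonical correlations (fewer if the latent width is below 10); the
#' configuration with the best fold-mean score wins, ties broken by grid
#' order. A fold whose training diverges scores `-Inf`.
#'
#' @param X,Y row-aligned matrices.
#' @param grid list of `dccae_config` objects.
#' @param folds number of folds (default 5, >= 2).
#' @param n_score number of leading correlations summed (default 10).
#' @return The winning `dccae_config`, with the per-config fold-mean
#'   scores attached as attribute `"cv_scores"`.
#' @export
cross_validate <- function(X, Y, grid, folds = 5, n_score = 10) {
  if (!length(grid)) stop("empty configuration grid")
  if (folds < 2) stop("folds must be >= 2")
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  fold_id <- rep_len(seq_len(folds), n)
  scores <- vapply(seq_along(grid), function(ci) {
    cfg <- grid[[ci]]
    fs <- vapply(seq_len(folds), function(f) {
      tr <- fold_id != f
      m <- tryCatch(train_dccae(X[tr, , drop = FALSE], Y[tr, , drop = FALSE], cfg),
                    error = function(e) NULL)
      if (is.null(m)) return(-Inf)
      r <- tryCatch(encode_and_cca(m, X[!tr, , drop = FALSE],
                                   Y[!tr, , drop = FALSE])$correlations,
                    error = function(e) NA_real_)
      s <- sum(r[seq_len(min(n_score, length(r)))])
      if (is.finite(s)) s else -Inf
    }, numeric(1))
    mean(fs)
  }, numeric(1))
  best <- grid[[which.max(scores)]]
  attr(best, "cv_scores") <- scores
  best
}

#' Default hyperparameter grid for cross-validation
#' @param ... arguments passed to every [dccae_config()] in the grid.
#' @return List of configs spanning lr in \{0.01, 0.001\} and
#'   lambda_recon in \{0.04, 0.08, 0.16\}.
#' @export
default_dccae_grid <- function(...) {
  g <- expand.grid(lr = c(0.01, 0.001), lambda = c(0.04, 0.08, 0.16))
  lapply(seq_len(nrow(g)), function(i)
    dccae_config(lr = g$lr[i], lambda_recon = g$lambda[i], ...))
}
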