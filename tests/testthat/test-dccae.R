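test_that("reconstruction loss follows the per-sample mean convention", {
  X <- matrix(c(1, 0), 1, 2)
  expect_identical(reconstruction_loss(X, X), 0)
  expect_identical(reconstruction_loss(X, matrix(0, 1, 2)), 1)
  set.seed(1)
  A <- matrix(rnorm(12), 3, 4); B <- matrix(rnorm(12), 3, 4)
  expect_equal(reconstruction_loss(A, B), sum((A - B)^2) / 3,
               tolerance = 1e-12)
  expect_error(reconstruction_loss(A, B[, 1:2]), "shape")
})

test_that("correlation loss equals minus k under perfect coupling and
           stays near zero for independent batches", {
  set.seed(2)
  FX <- matrix(rnorm(64 * 4), 64, 4)
  expect_equal(cca_loss(FX, FX, k = 4, r_x = 0, r_y = 0), -4,
               tolerance = 1e-8)
  # independent gaussian batches: each singular value is O(sqrt(d/n))
  FX <- matrix(rnorm(4000 * 4), 4000, 4)
  GY <- matrix(rnorm(4000 * 4), 4000, 4)
  expect_gt(cca_loss(FX, GY, k = 4), -4 * 4 * sqrt(4 / 4000))
  expect_error(cca_loss(FX[1:3, ], GY[1:3, ], k = 2), "batch")
  expect_error(cca_loss(FX, GY, k = 5), "latent width")
})

test_that("correlation-loss gradients match central finite differences", {
  set.seed(3)
  FX <- matrix(rnorm(32 * 4), 32, 4)
  GY <- matrix(rnorm(32 * 4), 32, 4)
  g <- cca_loss(FX, GY, k = 3, r_x = 1e-3, r_y = 1e-3, with_grad = TRUE)
  eps <- 1e-5
  for (i in c(1, 7, 20, 32)) for (j in 1:4) {
    up <- FX; up[i, j] <- up[i, j] + eps
    dn <- FX; dn[i, j] <- dn[i, j] - eps
    num <- (cca_loss(up, GY, 3, 1e-3, 1e-3) -
              cca_loss(dn, GY, 3, 1e-3, 1e-3)) / (2 * eps)
    expect_equal(g$grad_fx[i, j], num, tolerance = 1e-4)
    up <- GY; up[i, j] <- up[i, j] + eps
    dn <- GY; dn[i, j] <- dn[i, j] - eps
    num <- (cca_loss(FX, up, 3, 1e-3, 1e-3) -
              cca_loss(FX, dn, 3, 1e-3, 1e-3)) / (2 * eps)
    expect_equal(g$grad_gy[i, j], num, tolerance = 1e-4)
  }
})

test_that("config validation enforces the loss-weight and batch bounds", {
  expect_error(dccae_config(lambda_recon = 1.2), "lambda_recon")
  expect_error(dccae_config(latent = 10, k_corr = 12), "k_corr")
  expect_error(dccae_config(batch_size = 20, latent = 20), "batch_size")
})

test_that("training is deterministic and its loss trace decreases", {
  v <- tiny_views(n = 400, p = 12, q = 10, seed = 21)
  tr <- v$split_labels == "train"
  cfg <- dccae_config(hidden = 16L, latent = 4L, batch_size = 128L,
                      epochs = 60L, seed = 5)
  m1 <- train_dccae(v$X[tr, ], v$Y[tr, ], cfg)
  m2 <- train_dccae(v$X[tr, ], v$Y[tr, ], cfg)
  expect_identical(m1$loss_trace, m2$loss_trace)
  # smoothed (5-epoch mean) total loss is nonincreasing up to jitter
  sm <- stats::filter(m1$loss_trace[, "total"], rep(1 / 5, 5))
  sm <- sm[!is.na(sm)]
  rng <- max(sm) - min(sm)
  expect_true(all(diff(sm) < 0.02 * rng))
  expect_lt(sm[length(sm)], sm[1])
})

test_that("a pure autoencoder leaves the correlation objective untrained", {
  v <- tiny_views(n = 400, p = 12, q = 10, seed = 22)
  tr <- v$split_labels == "train"
  ae1 <- dccae_config(hidden = 16L, latent = 4L, k_corr = 4L,
                      lambda_recon = 1, batch_size = 128L, epochs = 30L,
                      seed = 6)
  ae2 <- ae1; ae2$k_corr <- 2L
  m1 <- train_dccae(v$X[tr, ], v$Y[tr, ], ae1)
  m2 <- train_dccae(v$X[tr, ], v$Y[tr, ], ae2)
  # reconstruction is learned...
  expect_lt(tail(m1$loss_trace[, "recon"], 1), m1$loss_trace[1, "recon"])
  # ...and the correlation term is untouched by the gradient: changing
  # k_corr (which only enters the correlation loss) leaves the parameter
  # trajectory identical
  expect_identical(m1$enc_x, m2$enc_x)
  expect_identical(m1$dec_y, m2$dec_y)
  expect_identical(m1$loss_trace[, "recon"], m2$loss_trace[, "recon"])
})

test_that("default-config DCCAE is competitive with CCA on planted data", {
  spec <- synthetic_spec(n_subjects = 2000, seed = 1)
  v <- generate_coupled_views(spec)
  tr <- v$split_labels == "train"
  cm <- fit_cca(v$X[tr, ], v$Y[tr, ], k = 20)
  r_cca <- cca_project(cm, v$X[!tr, ], v$Y[!tr, ])$correlations
  m <- train_dccae(v$X[tr, ], v$Y[tr, ], dccae_config(seed = 1))
  e <- encode_and_cca(m, v$X[tr, ], v$Y[tr, ], v$X[!tr, ], v$Y[!tr, ])
  expect_gte(mean(e$test_correlations[1:5]), mean(r_cca[1:5]) - 0.05)
  # architecture defaults: 100-unit hidden layer into a 20-dim latent
  expect_identical(m$config$hidden, 100L)
  expect_identical(m$config$latent, 20L)
  expect_identical(ncol(dccae_encode(m, v$X[tr, ], "X")), 20L)
  # train-side self-consistency of the projection path
  expect_equal(encode_and_cca(m, v$X[tr, ], v$Y[tr, ])$correlations,
               m$cca$train_correlations, tolerance = 1e-10)
  # dual-split screen is produced with the Bonferroni-corrected level
  expect_s3_class(e$screen, "component_screen")
  expect_equal(attr(e$screen, "alpha_corrected"), 0.05 / 20)
})

test_that("nonlinearity is non-inferior on tanh-mixed data and the linear
           ablation tracks plain CCA on linear data", {
  spec_t <- synthetic_spec(n_subjects = 2000, mixing = "tanh", seed = 1)
  vt <- generate_coupled_views(spec_t)
  tr <- vt$split_labels == "train"
  cfg <- dccae_config(seed = 1)
  mf <- train_dccae(vt$X[tr, ], vt$Y[tr, ], cfg)
  ma <- train_dccae(vt$X[tr, ], vt$Y[tr, ], ablate_linear(cfg))
  ef <- encode_and_cca(mf, vt$X[tr, ], vt$Y[tr, ], vt$X[!tr, ], vt$Y[!tr, ])
  ea <- encode_and_cca(ma, vt$X[tr, ], vt$Y[tr, ], vt$X[!tr, ], vt$Y[!tr, ])
  expect_gte(mean(ef$test_correlations[1:5]),
             mean(ea$test_correlations[1:5]) - 0.02)
})

test_that("ablation strips hidden layers down to one affine map", {
  cfg <- dccae_config(hidden = c(100L, 50L))
  ab <- ablate_linear(cfg)
  expect_identical(ab$hidden, integer(0))
  expect_error(ablate_linear(ab), "no hidden layer")
  v <- tiny_views(n = 200, p = 8, q = 8, seed = 23)
  m <- train_dccae(v$X, v$Y, dccae_config(hidden = integer(0), latent = 3L,
                                          batch_size = 64L, epochs = 3L,
                                          seed = 7))
  expect_length(m$enc_x, 1)  # single affine layer
})

test_that("linear encoder at zero reconstruction weight attains the CCA
           objective on well-conditioned data", {
  v <- tiny_views(n = 300, p = 8, q = 8, rho = c(0.8, 0.5), seed = 24)
  cfg <- dccae_config(hidden = integer(0), latent = 4L, k_corr = 4L,
                      lambda_recon = 0, r_x = 1e-4, r_y = 1e-4,
                      lr = 0.1, epochs = 2000L, batch_size = 300L, seed = 8)
  m <- train_dccae(v$X, v$Y, cfg)
  achieved <- sum(m$cca$train_correlations)
  target <- sum(fit_cca(v$X, v$Y, k = 4, ridge = 0)$train_correlations)
  expect_equal(achieved, target, tolerance = 0.02)
})

test_that("cross-validation prefers configurations that do not diverge", {
  v <- tiny_views(n = 250, p = 8, q = 8, seed = 25)
  good <- dccae_config(hidden = 8L, latent = 3L, batch_size = 64L,
                       epochs = 10L, seed = 9)
  expect_identical(cross_validate(v$X, v$Y, list(good), folds = 2),
                   good, ignore_attr = TRUE)
  bad <- good; bad$lr <- 1e150
  pick <- cross_validate(v$X, v$Y, list(bad, good), folds = 2, n_score = 3)
  expect_identical(pick$lr, good$lr)
  expect_identical(attr(pick, "cv_scores")[1], -Inf)
  # ties break in grid order
  pick2 <- cross_validate(v$X, v$Y, list(good, good), folds = 2, n_score = 3)
  expect_identical(pick2$seed, good$seed)
  expect_error(cross_validate(v$X, v$Y, list(), folds = 2), "empty")
})
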