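test_that("spec validation rejects ill-formed inputs", {
  expect_error(synthetic_spec(canonical_corrs = c(0.2, 0.6)), "nonincreasing")
  expect_error(synthetic_spec(canonical_corrs = c(1.2, 0.5)), "\\[0, 1\\]")
  expect_error(synthetic_spec(p_x = 2, p_y = 5,
                              canonical_corrs = c(0.5, 0.4, 0.3)),
               "exceeds min")
  expect_error(synthetic_spec(noise_sd = 0), "noise_sd")
  expect_error(
    synthetic_spec(outcome_effects = list(y = c(0.5, 0.2))),
    "length")
})

test_that("generated views have the configured shape and split", {
  spec <- synthetic_spec(n_subjects = 3302, p_x = 100, p_y = 100, seed = 2)
  v <- generate_coupled_views(spec)
  expect_identical(dim(v$X), c(3302L, 100L))
  expect_identical(dim(v$Y), c(3302L, 100L))
  expect_false(anyNA(v$X) || anyNA(v$Y))
  expect_equal(sum(v$split_labels == "train"), round(0.8 * 3302))
})

test_that("generation is byte-identical under a fixed seed", {
  spec <- synthetic_spec(n_subjects = 120, p_x = 10, p_y = 8,
                         canonical_corrs = c(0.5, 0.3), seed = 11)
  v1 <- generate_coupled_views(spec)
  v2 <- generate_coupled_views(spec)
  expect_identical(v1, v2)
  o1 <- generate_outcomes(v1, spec)
  o2 <- generate_outcomes(v2, spec)
  expect_identical(o1, o2)
  v3 <- generate_coupled_views(synthetic_spec(n_subjects = 120, p_x = 10,
                                              p_y = 8,
                                              canonical_corrs = c(0.5, 0.3),
                                              seed = 12))
  expect_false(identical(v1$X, v3$X))
})

test_that("planted factor coupling is exact within each split", {
  rho <- c(0.6, 0.4, 0.2)
  spec <- synthetic_spec(n_subjects = 600, p_x = 20, p_y = 20,
                         canonical_corrs = rho, seed = 5)
  v <- generate_coupled_views(spec)
  # stored latents are exactly orthonormal within each split
  for (s in levels(v$split_labels)) {
    rows <- v$split_labels == s
    z <- v$true_latents[rows, ]
    expect_equal(max(abs(crossprod(scale(z)) / (sum(rows) - 1) -
                           diag(3))), 0, tolerance = 1e-10)
  }
  # and held-out canonical correlations recover the planted values
  tr <- v$split_labels == "train"
  pr <- cca_project(fit_cca(v$X[tr, ], v$Y[tr, ], k = 3),
                    v$X[!tr, ], v$Y[!tr, ])
  expect_equal(pr$correlations, rho, tolerance = 0.05)
})

test_that("tanh mixing attenuates but preserves linear detectability", {
  spec_l <- synthetic_spec(n_subjects = 1500, p_x = 30, p_y = 30,
                           canonical_corrs = c(0.7), seed = 8)
  spec_t <- synthetic_spec(n_subjects = 1500, p_x = 30, p_y = 30,
                           canonical_corrs = c(0.7), mixing = "tanh",
                           seed = 8)
  vl <- generate_coupled_views(spec_l)
  vt <- generate_coupled_views(spec_t)
  tr <- vl$split_labels == "train"
  rl <- cca_project(fit_cca(vl$X[tr, ], vl$Y[tr, ], k = 1),
                    vl$X[!tr, ], vl$Y[!tr, ])$correlations[1]
  rt <- cca_project(fit_cca(vt$X[tr, ], vt$Y[tr, ], k = 1),
                    vt$X[!tr, ], vt$Y[!tr, ])$correlations[1]
  expect_gt(rt, 0.4)   # still detectable by a linear method
  expect_lt(rt, rl)    # but attenuated relative to linear mixing
})

test_that("outcome table carries covariates, sites and all outcomes", {
  spec <- synthetic_spec(n_subjects = 500, p_x = 10, p_y = 10, seed = 3)
  v <- generate_coupled_views(spec)
  o <- generate_outcomes(v, spec)
  expect_setequal(setdiff(names(o), c("subject_id", "site", "age", "sex",
                                      "split")),
                  names(spec$outcome_effects))
  expect_length(setdiff(names(o), c("subject_id", "site", "age", "sex",
                                    "split")), 11)  # 3 cognition + 8 CBCL
  expect_true(all(o$age >= 108 & o$age <= 132))
  expect_true(all(o$sex %in% 0:1))
  expect_equal(nlevels(o$site), spec$n_sites)
})

test_that("null outcome loadings give outcomes uncorrelated with latents", {
  worst <- 0
  for (i in 1:20) {
    spec <- synthetic_spec(n_subjects = 400, p_x = 10, p_y = 10,
                           site_sd = 0,
                           outcome_effects = list(y = c(0, 0, 0)),
                           seed = 400 + i)
    v <- generate_coupled_views(spec)
    o <- generate_outcomes(v, spec)
    resid <- residuals(lm(o$y ~ o$age + o$sex))
    worst <- max(worst, abs(cor(resid, v$true_latents)))
  }
  expect_lt(worst, 3 / sqrt(400))
})

test_that("site random-intercept variance matches the configured scale", {
  spec <- synthetic_spec(n_subjects = 4000, p_x = 10, p_y = 10,
                         n_sites = 30, site_sd = 0.5,
                         outcome_effects = list(y = c(0, 0, 0)), seed = 9)
  v <- generate_coupled_views(spec)
  o <- generate_outcomes(v, spec)
  fit <- lme4::lmer(y ~ age + sex + (1 | site), data = o, REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(fit))
  site_var <- vc$vcov[vc$grp == "site"]
  expect_lt(abs(site_var - 0.25), 0.3 * 0.25)
})

test_that("voxel dataset plants a recoverable change signal", {
  spec <- synthetic_spec(n_subjects = 15, p_x = 40, p_y = 10,
                         canonical_corrs = c(0.5, 0.3), seed = 6)
  vms <- generate_voxel_dataset(spec, grid_dim = c(6, 6, 6))
  expect_identical(dim(vms$baseline), dim(vms$followup))
  expect_true(all(vms$baseline >= 0) && all(vms$followup >= 0))
  mask <- build_mask(vms, threshold = 0.2)
  expect_identical(mask$include, vms$in_mask)
  cm <- apply_mask_and_delta(vms, vms, mask)
  expect_equal(unname(cm$values), unname(vms$planted_delta),
               tolerance = 1e-12)
})

test_that("zero planted change yields an all-zero delta matrix", {
  spec <- synthetic_spec(n_subjects = 5, p_x = 20, p_y = 5,
                         canonical_corrs = 0.5, seed = 7)
  vms <- generate_voxel_dataset(spec, grid_dim = c(5, 5, 5),
                                change_scale = 0)
  cm <- apply_mask_and_delta(vms, vms, build_mask(vms, 0.2))
  expect_true(all(cm$values == 0))
})

test_that("TSV and NIfTI round trips preserve the data", {
  spec <- synthetic_spec(n_subjects = 30, p_x = 6, p_y = 5,
                         canonical_corrs = c(0.5, 0.2), seed = 4)
  v <- generate_coupled_views(spec)
  d <- withr::local_tempdir()
  write_paired_views(v, d)
  v2 <- read_paired_views(d)
  expect_equal(v2$X, v$X, tolerance = 1e-12)
  expect_equal(v2$Y, v$Y, tolerance = 1e-12)
  expect_identical(v2$split_labels, v$split_labels)

  vms <- generate_voxel_dataset(spec, grid_dim = c(4, 4, 4))
  paths <- write_voxel_nifti(vms, d)
  expect_identical(read_voxel_nifti(paths[1]), unclass(vms$baseline))
  expect_identical(read_voxel_nifti(paths[2]), unclass(vms$followup))
})
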