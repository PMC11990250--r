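#' Specification for a synthetic coupled multimodal dataset
#'
#' Defines the population from which paired change-feature matrices,
#' voxel-map stand-ins and outcome tables are drawn. Two views share
#' `k_latent` latent factors; latent pair `j` is coupled at population
#' correlation `canonical_corrs[j]`. Features are random linear (or
#' tanh-squashed) mixtures of the view factors plus isotropic Gaussian
#' noise. Outcomes are linear in the shared latents plus age and sex
#' effects, a per-site random intercept and unit residual noise.
#'
#' @param n_subjects number of subjects (rows of both views).
#' @param p_x,p_y feature counts of view X and view Y.
#' @param canonical_corrs nonincreasing vector in \[0, 1\] of target
#'   population canonical correlations; its length sets `k_latent`.
#' @param mixing `"linear"` or `"tanh"`. Under `"tanh"` the factor-driven
#'   signal (not the noise) is passed through an elementwise tanh, so a
#'   linear method still sees attenuated coupling.
#' @param noise_sd standard deviation of the additive feature noise (> 0),
#'   relative to the unit per-feature signal variance. The default 0.05
#'   treats the features as PCA-score-like summaries that are mostly
#'   signal; raise it to stress the methods.
#' @param n_sites number of collection sites for the outcome table.
#' @param site_sd standard deviation of the per-site outcome random
#'   intercept.
#' @param outcome_effects named list mapping outcome name to a length
#'   `k_latent` vector of loadings on the shared latents (standardized
#'   latent scale). Defaults to three cognition change scores driven by
#'   latent 1 and eight behaviour syndrome scales driven by latent 2.
#' @param train_frac fraction of subjects labelled `"train"`.
#' @param seed integer seed; all generation is deterministic given it.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_subjects = 3302, p_x = 100, p_y = 100,
                           canonical_corrs = c(0.6, 0.4, 0.2),
                           mixing = c("linear", "tanh"),
                           noise_sd = 0.05, n_sites = 21, site_sd = 0.25,
                           outcome_effects = NULL,
                           train_frac = 0.8, seed = 1L) {
  mixing <- match.arg(mixing)
  k <- length(canonical_corrs)
  if (k < 1L) stop("canonical_corrs must have length >= 1")
  if (any(canonical_corrs < 0 | canonical_corrs > 1))
    stop("canonical_corrs must lie in [0, 1]")
  if (is.unsorted(rev(canonical_corrs)))
    stop("canonical_corrs must be nonincreasing")
  if (k > min(p_x, p_y))
    stop("k_latent (", k, ") exceeds min(p_x, p_y) = ", min(p_x, p_y))
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  if (site_sd < 0) stop("site_sd must be >= 0")
  if (n_sites < 1) stop("n_sites must be >= 1")
  if (train_frac <= 0 || train_frac >= 1) stop("train_frac must be in (0, 1)")
  if (is.null(outcome_effects))
    outcome_effects <- default_outcome_effects(k)
  lens <- vapply(outcome_effects, length, integer(1))
  if (length(outcome_effects) && any(lens != k))
    stop("every outcome_effects vector must have length k_latent = ", k)
  structure(list(
    n_subjects = as.integer(n_subjects), p_x = as.integer(p_x),
    p_y = as.integer(p_y), k_latent = as.integer(k),
    canonical_corrs = as.numeric(canonical_corrs), mixing = mixing,
    noise_sd = noise_sd, n_sites = as.integer(n_sites), site_sd = site_sd,
    outcome_effects = outcome_effects, train_frac = train_frac,
    seed = as.integer(seed)
  ), class = "synthetic_spec")
}

# 3 cognition change scores + 8 CBCL-style syndrome scales.
default_outcome_effects <- function(k) {
  load1 <- function(idx, val) {
    v <- numeric(k); v[min(idx, k)] <- val; v
  }
  cog <- list(fluid = load1(1, 0.5), crystallized = load1(1, 0.4),
              total_composite = load1(1, 0.5))
  syndromes <- c("anxious_depressed", "withdrawn_depressed",
                 "somatic_complaints", "social_problems", "thought_problems",
                 "attention_problems", "rule_breaking", "aggressive_behavior")
  beh <- lapply(syndromes, function(s) load1(2, 0.2))
  names(beh) <- syndromes
  c(cog, beh)
}

#' Generate a pair of coupled feature matrices
#'
#' Draws shared latents `z_j` once per subject; the X-side factor for
#' latent `j` is `z_j` itself and the Y-side factor is
#' `rho_j * z_j + sqrt(1 - rho_j^2) * e_j`. The latent draws are
#' orthonormalized in-sample (`z` columns exactly uncorrelated with unit
#' variance, `e` exactly orthogonal to `z`), so the factor pair `j` is
#' correlated at exactly `rho_j` within each analysis split, not merely
#' in expectation — planted-correlation recovery tests are then
#' analytic, and a null spec (`rho = 0`) yields exactly uncoupled splits.
#' Each view is the factors times a loading matrix with orthogonal
#' columns scaled to unit per-feature signal variance, optionally
#' tanh-squashed, plus `N(0, noise_sd^2)` feature noise.
#'
#' @param spec a [synthetic_spec()].
#' @return A `paired_views` list with row-aligned matrices `X`
#'   (`n x p_x`), `Y` (`n x p_y`), a `split_labels` factor
#'   (train/test), and `true_latents` (`n x k_latent`, the shared `z`),
#'   retained for recovery tests only.
#' @export
generate_coupled_views <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_subjects; k <- spec$k_latent
  set.seed(spec$seed)
  z <- matrix(stats::rnorm(n * k), n, k)
  e <- matrix(stats::rnorm(n * k), n, k)
  n_train <- round(spec$train_frac * n)
  split <- rep("test", n)
  split[sample.int(n, n_train)] <- "train"
  # exact coupling within each split: z columns orthonormal, e orthogonal
  # to z (falls back to the raw draws in a split too small to support it)
  for (s in c("train", "test")) {
    rows <- which(split == s)
    if (length(rows) <= k + 1L) next
    zs <- qr.Q(qr(scale(z[rows, , drop = FALSE], scale = FALSE)))
    es <- e[rows, , drop = FALSE]
    es <- es - zs %*% crossprod(zs, es)
    z[rows, ] <- matrix(as.numeric(scale(zs)), length(rows), k)
    e[rows, ] <- matrix(as.numeric(scale(es)), length(rows), k)
  }
  rho <- spec$canonical_corrs
  fx <- z
  fy <- sweep(z, 2, rho, `*`) + sweep(e, 2, sqrt(1 - rho^2), `*`)
  ax <- qr.Q(qr(matrix(stats::rnorm(spec$p_x * k), spec$p_x, k))) *
    sqrt(spec$p_x / k)
  ay <- qr.Q(qr(matrix(stats::rnorm(spec$p_y * k), spec$p_y, k))) *
    sqrt(spec$p_y / k)
  sig_x <- fx %*% t(ax)
  sig_y <- fy %*% t(ay)
  if (spec$mixing == "tanh") {
    sig_x <- tanh(sig_x)
    sig_y <- tanh(sig_y)
  }
  X <- sig_x + matrix(stats::rnorm(n * spec$p_x, sd = spec$noise_sd), n, spec$p_x)
  Y <- sig_y + matrix(stats::rnorm(n * spec$p_y, sd = spec$noise_sd), n, spec$p_y)
  ids <- sprintf("S%05d", seq_len(n))
  rownames(X) <- rownames(Y) <- ids
  colnames(X) <- sprintf("x%03d", seq_len(spec$p_x))
  colnames(Y) <- sprintf("y%03d", seq_len(spec$p_y))
  structure(list(X = X, Y = Y,
                 split_labels = factor(split, levels = c("train", "test")),
                 true_latents = z, subject_id = ids, spec = spec),
            class = "paired_views")
}

#' Generate an outcome table driven by the shared latents
#'
#' Each outcome is `loadings %*% true_latents` plus a small age effect
#' (0.01 per month, age uniform on 108--132 months), a sex effect (0.2,
#' sex Bernoulli(0.5)), a per-site Gaussian random intercept with sd
#' `site_sd`, and unit-variance residual noise. Sites are assigned
#' uniformly at random. Deterministic given `spec$seed` (an offset
#' substream, so views and outcomes are independently reproducible).
#'
#' @param views a `paired_views` object.
#' @param spec the [synthetic_spec()] used to generate `views`.
#' @return A data frame with columns `subject_id`, `site`, `age`, `sex`,
#'   then one column per outcome; `split` is carried along as an extra
#'   column for convenience.
#' @export
generate_outcomes <- function(views, spec) {
  stopifnot(inherits(views, "paired_views"), inherits(spec, "synthetic_spec"))
  if (!length(spec$outcome_effects)) stop("outcome_effects must be nonempty")
  lens <- vapply(spec$outcome_effects, length, integer(1))
  if (any(lens != spec$k_latent))
    stop("outcome loading vectors must have length k_latent = ", spec$k_latent)
  n <- nrow(views$X)
  set.seed(spec$seed + 104729L)  # fixed offset substream
  age  <- stats::runif(n, 108, 132)
  sex  <- stats::rbinom(n, 1, 0.5)
  site <- sample.int(spec$n_sites, n, replace = TRUE)
  site_int <- stats::rnorm(spec$n_sites, sd = spec$site_sd)
  z <- views$true_latents
  out <- data.frame(subject_id = views$subject_id,
                    site = factor(site), age = age, sex = sex,
                    stringsAsFactors = FALSE)
  for (nm in names(spec$outcome_effects)) {
    beta <- spec$outcome_effects[[nm]]
    out[[nm]] <- as.numeric(z %*% beta) + 0.01 * (age - 120) + 0.2 * sex +
      site_int[site] + stats::rnorm(n)
  }
  out$split <- views$split_labels
  out
}

#' Generate a small voxel-map dataset with planted change
#'
#' Builds per-subject baseline 3D maps on a small grid and a follow-up
#' set equal to baseline plus a planted change: the in-mask voxels of the
#' change map are, subject by subject, a (rescaled) row of a coupled view
#' generated from `spec`, smoothed only in the sense that in-mask voxels
#' form a contiguous raster block. Baseline in-mask voxels have
#' cross-subject mean well above `mask_threshold` and out-of-mask voxels
#' well below it, so the downstream mask recovers the planted support.
#' All values are kept nonnegative by scaling the planted change.
#'
#' @param spec a [synthetic_spec()]; `p_x` in-mask voxels are used.
#' @param grid_dim 3-vector of grid dimensions (product must be >= `p_x`;
#'   kept small, e.g. at most 20^3 voxels).
#' @param mask_threshold the mask threshold the maps are built around.
#' @param change_scale maximum absolute planted change after rescaling.
#' @return A `voxel_map_set` list with 4D arrays `baseline` and
#'   `followup` (x, y, z, subject), `modality`, the `in_mask` logical 3D
#'   array actually planted, and `planted_delta`, the n x p_x matrix of
#'   in-mask changes (raster order) that preprocessing should recover.
#' @export
generate_voxel_dataset <- function(spec, grid_dim = c(8, 8, 8),
                                   mask_threshold = 0.2,
                                   change_scale = 0.2) {
  stopifnot(inherits(spec, "synthetic_spec"), length(grid_dim) == 3)
  nvox <- prod(grid_dim)
  if (nvox > 20^3) stop("grid too large; keep at most 20^3 voxels")
  if (nvox < spec$p_x)
    stop("grid has ", nvox, " voxels but spec$p_x = ", spec$p_x)
  n <- spec$n_subjects
  views <- generate_coupled_views(spec)
  set.seed(spec$seed + 15485863L)
  # first p_x voxels in raster order are in-mask
  in_mask <- array(FALSE, grid_dim)
  in_mask[seq_len(spec$p_x)] <- TRUE
  base_mean <- ifelse(in_mask, mask_threshold + 0.4, mask_threshold / 2)
  baseline <- array(0, c(grid_dim, n))
  followup <- array(0, c(grid_dim, n))
  delta_raw <- views$X
  mx <- max(abs(delta_raw))
  scl <- if (mx > 0) change_scale / mx else 1
  delta <- delta_raw * scl
  for (i in seq_len(n)) {
    b <- base_mean + array(stats::runif(nvox, 0, 0.05), grid_dim)
    d <- array(0, grid_dim)
    d[seq_len(spec$p_x)] <- delta[i, ]
    baseline[, , , i] <- b
    followup[, , , i] <- pmax(b + d, 0)
  }
  structure(list(baseline = baseline, followup = followup, modality = "GM",
                 in_mask = in_mask, planted_delta = delta,
                 subject_id = views$subject_id),
            class = "voxel_map_set")
}

#' Write paired views to tab-separated files
#'
#' One TSV per view: subject IDs in the first column, feature names in
#' the header. A third file records the train/test split.
#'
#' @param views a `paired_views` object.
#' @param dir output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_paired_views <- function(views, dir) {
  stopifnot(inherits(views, "paired_views"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("view_x.tsv", "view_y.tsv", "split.tsv"))
  for (i in 1:2) {
    m <- views[[c("X", "Y")[i]]]
    df <- data.frame(subject_id = views$subject_id, m, check.names = FALSE)
    utils::write.table(df, paths[i], sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  utils::write.table(
    data.frame(subject_id = views$subject_id,
               split = as.character(views$split_labels)),
    paths[3], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Read paired views written by [write_paired_views()]
#' @param dir directory containing `view_x.tsv`, `view_y.tsv`, `split.tsv`.
#' @return A `paired_views` object (without `true_latents`).
#' @export
read_paired_views <- function(dir) {
  rd <- function(f) utils::read.delim(file.path(dir, f), check.names = FALSE)
  dx <- rd("view_x.tsv"); dy <- rd("view_y.tsv"); sp <- rd("split.tsv")
  stopifnot(identical(dx$subject_id, dy$subject_id),
            identical(dx$subject_id, sp$subject_id))
  X <- as.matrix(dx[-1]); Y <- as.matrix(dy[-1])
  rownames(X) <- rownames(Y) <- dx$subject_id
  structure(list(X = X, Y = Y,
                 split_labels = factor(sp$split, levels = c("train", "test")),
                 true_latents = NULL, subject_id = dx$subject_id,
                 spec = NULL),
            class = "paired_views")
}

#' Write a voxel-map set as 4D NIfTI volumes
#'
#' @param vms a `voxel_map_set`.
#' @param dir output directory.
#' @return Invisibly, the two file paths (`<modality>_baseline.nii.gz`,
#'   `<modality>_followup.nii.gz`).
#' @export
write_voxel_nifti <- function(vms, dir) {
  stopifnot(inherits(vms, "voxel_map_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pb <- file.path(dir, paste0(vms$modality, "_baseline.nii.gz"))
  pf <- file.path(dir, paste0(vms$modality, "_followup.nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(vms$baseline), pb)
  RNifti::writeNifti(RNifti::asNifti(vms$followup), pf)
  invisible(c(pb, pf))
}

#' Read a 4D NIfTI volume into a plain array
#' @param path NIfTI file path.
#' @return A numeric array.
#' @export
read_voxel_nifti <- function(path) {
  a <- RNifti::readNifti(path)
  array(as.numeric(a), dim = dim(a))
}
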