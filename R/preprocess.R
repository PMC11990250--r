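#' Build a voxel mask from baseline maps
#'
#' A voxel enters the mask iff its cross-subject baseline mean strictly
#' exceeds `threshold`. The same baseline-derived mask is meant to be
#' applied to both timepoints of the modality.
#'
#' @param baseline_maps a `voxel_map_set`, or a 4D array (x, y, z,
#'   subject) of baseline maps.
#' @param threshold mask threshold (default 0.2).
#' @return An object of class `voxel_mask`: list with logical 3D array
#'   `include` and the `threshold` used.
#' @export
build_mask <- function(baseline_maps, threshold = 0.2) {
  arr <- if (inherits(baseline_maps, "voxel_map_set"))
    baseline_maps$baseline else baseline_maps
  if (length(dim(arr)) != 4) stop("baseline maps must be a 4D array")
  if (dim(arr)[4] < 1) stop("need at least one subject")
  m <- apply(arr, 1:3, mean)
  include <- m > threshold
  if (!any(include))
    stop("mask is empty: no voxel has baseline mean > ", threshold)
  structure(list(include = include, threshold = threshold),
            class = "voxel_mask")
}

#' Change matrix from masked baseline and follow-up maps
#'
#' Entry (i, j) is follow-up minus baseline for subject i at the j-th
#' in-mask voxel. Columns follow the fixed raster (column-major array)
#' order of the in-mask voxels.
#'
#' @param baseline,followup `voxel_map_set` objects or 4D arrays with
#'   identical dimensions and aligned subjects.
#' @param mask a `voxel_mask` from [build_mask()].
#' @return A `change_matrix`: list with `values` (n_subjects x
#'   n_in_mask_voxels), `subject_ids`, and `modality`.
#' @export
apply_mask_and_delta <- function(baseline, followup, mask) {
  modality <- if (inherits(baseline, "voxel_map_set")) baseline$modality else "map"
  ids <- if (inherits(baseline, "voxel_map_set")) baseline$subject_id else NULL
  if (inherits(baseline, "voxel_map_set")) {
    if (inherits(followup, "voxel_map_set") &&
        !identical(baseline$subject_id, followup$subject_id))
      stop("baseline and follow-up subjects are not aligned")
  }
  b <- if (inherits(baseline, "voxel_map_set")) baseline$baseline else baseline
  f <- if (inherits(followup, "voxel_map_set")) followup$followup else followup
  if (!identical(dim(b), dim(f))) stop("baseline/follow-up shape mismatch")
  if (!identical(dim(b)[1:3], dim(mask$include)))
    stop("mask shape does not match the maps")
  n <- dim(b)[4]
  if (is.null(ids)) ids <- sprintf("S%05d", seq_len(n))
  idx <- which(mask$include)
  nv <- prod(dim(b)[1:3])
  bm <- matrix(b, nrow = nv, ncol = n)[idx, , drop = FALSE]
  fm <- matrix(f, nrow = nv, ncol = n)[idx, , drop = FALSE]
  vals <- t(fm - bm)
  rownames(vals) <- ids
  structure(list(values = vals, subject_ids = ids, modality = modality),
            class = "change_matrix")
}

#' Principal component reduction of a change matrix
#'
#' Columns are centered (not scaled; voxelwise changes share units) and
#' the top `K` right singular vectors taken as loadings. The sign of
#' each component is fixed so its largest-magnitude loading entry is
#' positive, making results stable across platforms.
#'
#' @param delta a `change_matrix` or a plain numeric matrix (subjects in
#'   rows).
#' @param K number of components to keep (default 100, the feature count
#'   used throughout the pipeline). Must satisfy `K <= min(n - 1, v)`.
#' @return A list with `model` (class `pca_model`: `mean_vector`,
#'   `loadings` v x K with orthonormal columns, `explained_variance_ratio`,
#'   `K`) and `scores` (n x K centered projections).
#' @export
fit_pca <- function(delta, K = 100) {
  X <- if (inherits(delta, "change_matrix")) delta$values else as.matrix(delta)
  n <- nrow(X); v <- ncol(X)
  if (K > min(n - 1, v))
    stop("K = ", K, " exceeds min(n - 1, v) = ", min(n - 1, v))
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  sv <- svd(Xc, nu = 0, nv = K)
  loadings <- sv$v
  # sign convention: largest |loading| entry positive (first on ties)
  for (j in seq_len(K)) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) loadings[, j] <- -loadings[, j]
  }
  eig <- sv$d^2 / (n - 1)
  total_var <- sum(Xc^2) / (n - 1)
  ratio <- eig[seq_len(K)] / total_var
  scores <- Xc %*% loadings
  colnames(scores) <- colnames(loadings) <- sprintf("PC%03d", seq_len(K))
  model <- structure(list(mean_vector = mu, loadings = loadings,
                          explained_variance_ratio = ratio, K = as.integer(K)),
                     class = "pca_model")
  list(model = model, scores = scores)
}

#' Project new data onto a fitted PCA basis
#' @param model a `pca_model`.
#' @param X matrix with the same column count as the training data.
#' @return n x K score matrix (centered with the training mean).
#' @export
pca_project <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != length(model$mean_vector))
    stop("column count does not match the fitted PCA")
  sweep(X, 2, model$mean_vector) %*% model$loadings
}

#' Reconstruct data from PCA scores
#' @param model a `pca_model`.
#' @param scores n x K score matrix.
#' @return n x v matrix, the rank-K reconstruction.
#' @export
pca_backproject <- function(model, scores) {
  scores <- as.matrix(scores)
  if (ncol(scores) != model$K) stop("score column count does not match K")
  sweep(scores %*% t(model$loadings), 2, model$mean_vector, `+`)
}

#' Cumulative explained-variance curve
#' @param model a fitted `pca_model`.
#' @return Numeric vector of cumulative explained-variance ratios
#'   (nondecreasing, final value at most 1).
#' @export
variance_report <- function(model) {
  stopifnot(inherits(model, "pca_model"))
  cumsum(model$explained_variance_ratio)
}
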