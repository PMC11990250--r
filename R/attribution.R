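#' Latent representation of one view under a fitted model
#'
#' For a linear CCA model this is the centered data times the view's
#' canonical weights; for a DCCAE it is the encoder output passed
#' through the post-hoc canonical weights. Both give an n x k matrix of
#' canonical variates.
#'
#' @param model a `cca_model` or `dccae_model`.
#' @param X data matrix for the chosen view.
#' @param view `"X"` or `"Y"`.
#' @return n x k latent matrix.
#' @export
latent_representation <- function(model, X, view = c("X", "Y")) {
  view <- match.arg(view)
  X <- as.matrix(X)
  if (inherits(model, "cca_model")) {
    w <- if (view == "X") model$u else model$v
    ctr <- if (view == "X") model$center_x else model$center_y
    if (ncol(X) != nrow(w)) stop("feature count outside model input width")
    sweep(X, 2, ctr) %*% w
  } else if (inherits(model, "dccae_model")) {
    enc <- dccae_encode(model, X, view)
    w <- if (view == "X") model$cca$u else model$cca$v
    ctr <- if (view == "X") model$cca$center_x else model$cca$center_y
    sweep(enc, 2, ctr) %*% w
  } else stop("model must be a cca_model or dccae_model")
}

#' Occlusion-based feature contributions to the latent components
#'
#' For each input feature j: set column j to zero (all other features
#' unchanged), recompute the latent representation, subtract the
#' original, and average the differences over samples — giving one
#' length-k shift vector per feature. Stacking them yields the
#' feature x component contribution score matrix; the signed means are
#' stored, with absolute values used only for ranking.
#'
#' @param model a fitted `cca_model` or `dccae_model`.
#' @param X the evaluation-split data of the chosen view.
#' @param view `"X"` or `"Y"`.
#' @return A `contribution_matrix`: list with `scores`
#'   (n_features x k, signed), `abs_scores`, and `view`.
#' @export
occlusion_contributions <- function(model, X, view = c("X", "Y")) {
  view <- match.arg(view)
  X <- as.matrix(X)
  base <- latent_representation(model, X, view)
  k <- ncol(base); p <- ncol(X)
  scores <- matrix(0, p, k)
  for (j in seq_len(p)) {
    Xo <- X
    Xo[, j] <- 0
    shifted <- latent_representation(model, Xo, view)
    scores[j, ] <- colMeans(shifted - base)
  }
  rownames(scores) <- colnames(X)
  structure(list(scores = scores, abs_scores = abs(scores), view = view),
            class = "contribution_matrix")
}

#' Top contributing features for one component
#'
#' Features ranked by descending absolute contribution score; ties are
#' broken in favour of the lower feature index.
#'
#' @param contribs a `contribution_matrix`.
#' @param component component index (1-based).
#' @param top_k number of features to return (default 5).
#' @return Integer vector of feature indices, ranked.
#' @export
top_features <- function(contribs, component, top_k = 5) {
  stopifnot(inherits(contribs, "contribution_matrix"))
  if (component > ncol(contribs$scores)) stop("component index out of range")
  a <- contribs$abs_scores[, component]
  if (top_k > length(a)) stop("top_k exceeds the number of features")
  order(-a, seq_along(a))[seq_len(top_k)]
}

#' Back-project component weights to a voxel map
#'
#' Maps a length-K weight vector over PCA features back to voxel space
#' (`loadings %*% weights`) and scatters the result into the in-mask
#' voxel positions; out-of-mask voxels are zero and signs are preserved,
#' so positive and negative regions remain distinguishable.
#'
#' @param component_weights numeric vector of length `pca_model$K`.
#' @param pca_model a fitted `pca_model`.
#' @param mask a `voxel_mask` whose in-mask voxel count equals the PCA
#'   input width.
#' @return 3D numeric array with the mask's dimensions.
#' @export
backproject_weights <- function(component_weights, pca_model, mask) {
  stopifnot(inherits(pca_model, "pca_model"), inherits(mask, "voxel_mask"))
  if (length(component_weights) != pca_model$K)
    stop("weight vector length must equal the PCA component count")
  if (sum(mask$include) != nrow(pca_model$loadings))
    stop("mask voxel count does not match the PCA input width")
  vox <- as.numeric(pca_model$loadings %*% component_weights)
  out <- array(0, dim(mask$include))
  out[mask$include] <- vox
  out
}
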