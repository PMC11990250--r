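---
title: "Methods: coupled latent growth analysis of paired multimodal change maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coupled latent growth analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Longitudinal multimodal imaging studies ask whether two tissue
compartments change *together*: does the two-year change in gray-matter
density (GM) share latent structure with the change in white-matter
fractional anisotropy (FA), and do the shared components track changes
in cognition and behaviour? `growthcca` implements that analysis as a
pipeline of five stages, each usable on its own:

1. **preprocess** — mask voxels by baseline mean, form per-subject
   change maps (follow-up minus baseline), reduce each modality to
   principal-component features;
2. **cca** — linear canonical correlation analysis with an 80/20
   train/test split and a dual-split significance screen;
3. **dccae** — a deep CCA autoencoder: per-view MLP encoders/decoders
   trained on a weighted sum of a correlation loss and reconstruction
   loss, with a post-hoc linear CCA on the encodings;
4. **attribution** — occlusion-based contribution scores of input
   features to latent components, and back-projection of linear weights
   to voxel maps;
5. **evaluation** — mixed-effects association of components with
   outcome changes (site random intercepts), combined variance
   explained, and CCA-vs-DCCAE component correlation.

Because cohort data of this kind is controlled-access, the package
ships a synthetic-data generator that plants known canonical structure;
every stage is validated against it.

## Models

### Linear CCA

Given row-aligned matrices $X \in \mathbb{R}^{n\times p}$ and
$Y \in \mathbb{R}^{n\times q}$, CCA finds weight matrices $u, v$
maximizing $\mathrm{corr}(Xu_j, Yv_j)$ subject to unit variance and
within-view orthogonality of successive variates. `fit_cca()` solves
the SVD of the whitened cross-covariance
$(\Sigma_X + r I)^{-1/2}\,\Sigma_{XY}\,(\Sigma_Y + r I)^{-1/2}$.
The ridge $r$ defaults to 2% of the mean feature variance per view.
That default matters: at $p = q = 100$ features and a few thousand
subjects, the largest *null* canonical correlation is approximately
$\sqrt{p/n} + \sqrt{q/n} \approx 0.4$, so unregularized whitening lets
sampling noise dominate weakly coupled directions. A 2% ridge shrinks
noise-level directions while leaving strong signal essentially
untouched; weights are rescaled afterwards so training variates have
exactly unit sample variance.

Two conventions make results reproducible across platforms: component
signs are fixed so that $\mathrm{corr}(Xu_j, Yv_j) \ge 0$ and the
largest-magnitude entry of $u_j$ is positive; and the stored
`train_correlations` are the Pearson correlations of the training
variates (identical to the singular values at $r = 0$). Under a
positive ridge the ordering follows the regularized singular values, so
the raw training Pearson correlations of overfit noise components can
occasionally exceed a later planted component — the dual-split screen,
not the ordering, decides significance.

Component significance uses the exact $t$ transform
$t = r\sqrt{n-2}/\sqrt{1-r^2}$ with a two-sided p-value, Bonferroni
corrected over the 20 latent dimensions ($0.05/20 = 0.0025$), and a
component counts only if it passes in **both** the training and the
held-out split. We use the per-component correlation test rather than
sequential Wilks/Bartlett statistics because each component pair is
reported individually.

### Deep CCA autoencoder

Each view gets an encoder $f$ (by default a 100-unit tanh hidden layer
into a 20-dimensional linear latent layer) and a mirrored decoder. The
training objective on a minibatch is

$$(1-\lambda)\,L_{\text{corr}}(f(X), g(Y)) \;+\;
  \lambda\,\bigl(\mathrm{MSE}(X,\hat X) + \mathrm{MSE}(Y,\hat Y)\bigr),$$

with $\lambda = 0.08$ on the reconstruction term and therefore $0.92$
on the correlation term. $L_{\text{corr}}$ is minus the sum of the
top-$k$ singular values of the whitened cross-covariance of the two
latent batches (covariances batch-centered, $1/(n-1)$ scaling, ridge
$r_x = r_y$ on the diagonals), and its analytic gradient is
backpropagated; the gradient is verified against central finite
differences in the test suite. Reconstruction error uses the
per-sample mean convention (feature dimension summed, sample dimension
averaged).

Optimization is plain minibatch gradient descent (momentum available
but off by default), learning rate 0.01, batch size 256, 150 epochs.
The batch size must exceed the latent width or the batch covariance is
rank-deficient; ragged tail batches smaller than the latent width are
skipped. Hyperparameters can be chosen by `cross_validate()`:
five-fold CV scoring each configuration by the mean over folds of the
sum of the first 10 validation-fold canonical correlations, ties broken
by grid order, divergent folds scored $-\infty$.

Numerical choices worth knowing:

* **Loss ridge $r_x = r_y = 0.1$.** A 20-dimensional latent covariance
  estimated from 256 samples is noisy; with a weak ridge the encoder
  overfits batch-level correlations and loses held-out correlation
  relative to its own linear ablation. The strong ridge only smooths
  the training signal — the hard unit-variance/orthogonality
  constraints are enforced by the post-hoc CCA, which is fitted on the
  full-training encodings after training and supplies the weights used
  for projection and screening.
* **Initialization** is Glorot-uniform; all randomness (init and batch
  shuffling) derives from `config$seed`, so a fixed configuration and
  seed reproduce the final loss exactly in single-threaded BLAS.
* **Divergence** (non-finite loss) aborts with the loss trace in the
  error message rather than returning a broken model.

`ablate_linear()` removes the hidden layers, leaving a single affine
map per view. On linearly mixed data this ablation tracks plain CCA
closely (the package's tests require the mean top-5 held-out
correlation to agree within 0.05), which is the built-in reference
point for judging whether nonlinearity buys anything on a given
dataset.

### Occlusion attribution

For a fitted model and an evaluation matrix, each input feature $j$ is
set to zero in turn (all other features untouched), the latent
representation is recomputed, and the mean over samples of the shift in
each latent dimension forms row $j$ of the contribution matrix
(features × components; 100 × 20 at the default sizes). Signed means
are stored; absolute values are used only for ranking (`top_features()`,
ties to the lower index). For a linear encoder with weight matrix $W$
the occlusion shift is analytically $-\bar{x}_j W[j,\cdot]$, which the
tests verify to 1e-8 — the nonlinear path is the same code with the
encoder swapped in. Occlusion operates in the PCA-feature space the
models consume, with a zero baseline (the features are centered scores,
so zero is the training mean); contributions are computed on the
training split unless the caller passes other data.
`backproject_weights()` maps any length-$K$ weight vector over PCA
features back to a voxel map through the PCA loadings, preserving sign,
with zeros outside the mask.

### Mixed-effects association and variance explained

Each component score is related to each outcome change with
`outcome ~ score + age + sex + (1 | site)`, fitted by REML (lme4), on
the held-out split. The reported p-value is the two-sided Wald normal
p from the fixed-effect $t$ ratio. A boundary fit (site variance
estimated at zero) triggers a warning and reports the boundary fit,
which then matches OLS to numerical precision. No multiple-testing
correction is applied across components × outcomes — a caveat carried
over deliberately, since the association tables are descriptive.

"Variance explained" by a component set is defined as 100 × the
increment in the *marginal* (fixed-effects) $R^2$ — Nakagawa's
$\mathrm{var}(X\hat\beta) / (\mathrm{var}(X\hat\beta) +
\hat\sigma^2_{\text{site}} + \hat\sigma^2_\varepsilon)$ — of the full
model over a covariates-only model. This is a documented choice among
several defensible definitions (conditional $R^2$, plain OLS $R^2$);
the increment is clamped at zero since marginal $R^2$ of nested mixed
models is not guaranteed monotone. Cross-method agreement between CCA
and DCCAE components is summarized by all-pairs Pearson correlations,
retaining pairs with $|r| > 0.15$; sign flips between methods are
expected (component signs are arbitrary) and handled by the
absolute-value rule.

## The synthetic-data generator

`synthetic_spec()` + `generate_coupled_views()` emulate the statistical
structure the pipeline assumes: $k$ shared latent factors $z_j$, an
X-side factor equal to $z_j$ and a Y-side factor
$\rho_j z_j + \sqrt{1-\rho_j^2}\, e_j$, so latent pair $j$ couples at
exactly $\rho_j$; loading matrices with orthogonal columns scaled to
unit per-feature signal variance; isotropic Gaussian feature noise; and
an optional elementwise tanh on the factor-driven signal (noise added
afterwards) for mildly nonlinear mixing that a linear method still
detects in attenuated form.

Two design points deserve emphasis:

* **Exact in-split coupling.** The latent draws are orthonormalized
  within each train/test split ($z$ columns exactly uncorrelated with
  unit variance, $e$ exactly orthogonal to $z$). Planted correlations
  are then exact sample quantities per split, which makes recovery
  tests analytic instead of statistical. Orthonormalizing across the
  *full* sample instead would be wrong in a subtle way: an exactly-zero
  full-sample correlation forces the test-split covariance to mirror
  the training covariance with a factor $-n_{\text{train}}/n_{\text{test}}$,
  so under a null spec spurious training correlations would reappear as
  large significant test correlations.
* **Noise scale.** `noise_sd` defaults to 0.05 relative to unit signal
  variance: the features stand in for PCA scores, which are already
  mostly signal. The default matters because canonical *direction*
  estimation at $p = 100$ is limited by the noise floor described
  above, independently of the noise scale, unless the CCA ridge
  dominates the residual variance. Raising `noise_sd` is the intended
  way to stress the methods.

Outcomes are `loadings · z` plus an age effect (0.01 per month, age
uniform on 108–132 months), a sex effect (0.2, sex Bernoulli(0.5)), a
per-site Gaussian intercept (21 sites, sd 0.25 by default) and unit
residual noise. The default outcome set — three cognition change
scores loading 0.5/0.4/0.5 on latent 1 and eight behaviour syndrome
scales loading 0.2 on latent 2 — encodes plausible standardized effect
sizes; no published values exist for them, so they are configuration,
not claims. Effect sizes are on the standardized latent scale.
`generate_voxel_dataset()` additionally wraps a view into small 4D
baseline/follow-up volumes whose in-mask change equals the (rescaled)
view rows, exercising the NIfTI path end to end.

What the generator does *not* emulate: real GM/FA spatial covariance,
anatomical geometry, site effects in the images themselves,
registration or segmentation artifacts, or missing data. Passing tests
therefore demonstrate the correctness of the computations and the
calibration of the screening rules under the planted model — not that
any particular real cohort satisfies that model.

## Problem sizes and defaults used in the checks

The packaged tests and the acceptance script run at sizes chosen to
make the statistical checks sharp on a single CPU: canonical-correlation
recovery at $n = 3000$, $p = q = 100$; DCCAE head-to-heads at
$n = 2000$ with the full 150-epoch schedule; null calibration over 20
replicates of 20 components at $n = 500$, $p = q = 25$; association
calibration over 100 replicate mixed-model fits; variance-explained
recovery over 20 replicates at $n = 3000$. The analysis drivers under
`analysis/` run the complete cohort-scale workflow (n = 3302) in a few
minutes.

## Known limitations

* Train/test splitting happens after PCA in the main pipeline order
  (PCA precedes the split), so PCA sees test subjects — a mild leakage
  accepted to mirror the pipeline being modelled; significance checks
  rely on the split only at the CCA stage and later.
* The occlusion score for strongly correlated features attributes
  shared signal to whichever feature is occluded; it is a local,
  one-at-a-time measure.
* The DCCAE optimizes a batch-level surrogate of the correlation
  objective; the cross-view orthogonality of distinct components is
  guaranteed only by the post-hoc CCA, not during descent.
* Marginal-$R^2$ increments can slightly exceed the planted variance
  share when covariate and component estimates compete; the tests bound
  the null inflation by the analytic $100(a+b)/n$ term on replicate
  means.
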