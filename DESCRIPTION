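Package: growthcca
Title: Coupled Latent Growth Analysis of Paired Multimodal Change Maps
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Analysis pipeline for extracting maximally correlated latent
    growth components from paired longitudinal neuroimaging modalities
    (e.g. gray-matter density and white-matter fractional anisotropy
    change maps). Implements masked change-matrix construction with PCA
    feature reduction, linear canonical correlation analysis with
    dual-split significance screening, a deep CCA autoencoder (DCCAE)
    trained on a weighted sum of a top-k canonical-correlation loss and
    reconstruction loss, occlusion-based attribution of latent components
    to input features with voxel back-projection, and mixed-effects
    association of components with outcome changes using site random
    intercepts. Includes a synthetic-data generator that plants known
    canonical structure so every stage is testable without restricted
    cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
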