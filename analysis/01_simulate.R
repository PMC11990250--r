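#!/usr/bin/env Rscript
# Generate the synthetic study cohort: two 3302 x 100 change-feature
# matrices (gray-matter-density-like and FA-like) coupled through three
# latent growth factors at canonical correlations 0.6 / 0.4 / 0.2, plus
# an outcome table (3 cognition change scores, 8 behaviour syndromes,
# age, sex, 21 sites). Full matrices go to scratch/ (large); small
# summaries to results/.

library(growthcca)

dir.create("results", showWarnings = FALSE)
dir.create("scratch/sim", showWarnings = FALSE, recursive = TRUE)

spec <- synthetic_spec(n_subjects = 3302, p_x = 100, p_y = 100,
                       canonical_corrs = c(0.6, 0.4, 0.2), seed = 1)
views <- generate_coupled_views(spec)
outcomes <- generate_outcomes(views, spec)

write_paired_views(views, "scratch/sim")
write.csv(outcomes, "scratch/sim/outcomes.csv", row.names = FALSE)

# a small voxel-map cohort exercising the image path end to end
vspec <- synthetic_spec(n_subjects = 200, p_x = 100, p_y = 20,
                        canonical_corrs = c(0.6, 0.4, 0.2), seed = 1)
vms <- generate_voxel_dataset(vspec, grid_dim = c(8, 8, 8))
write_voxel_nifti(vms, "scratch/sim")

summary_tab <- data.frame(
  quantity = c("subjects", "features_per_view", "train_fraction",
               "planted_rho_1", "planted_rho_2", "planted_rho_3",
               "outcome_columns", "sites"),
  value = c(spec$n_subjects, spec$p_x, spec$train_frac,
            spec$canonical_corrs, length(spec$outcome_effects),
            spec$n_sites))
write.table(summary_tab, "results/01_cohort_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("cohort:", nrow(views$X), "subjects x", ncol(views$X), "+",
    ncol(views$Y), "features;", length(spec$outcome_effects),
    "outcomes;", spec$n_sites, "sites\n")
cat("voxel demo:", paste(dim(vms$baseline), collapse = " x "), "\n")
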