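#!/usr/bin/env Rscript
# Linear CCA on the coupled feature matrices: fit 20 component pairs on
# the 80% training split, project the held-out 20%, and screen
# components at the Bonferroni-corrected level (p < 0.0025 in BOTH
# splits).

library(growthcca)

views <- read_paired_views("scratch/sim")
tr <- views$split_labels == "train"

model <- fit_cca(views$X[tr, ], views$Y[tr, ], k = 20)
pr_test <- cca_project(model, views$X[!tr, ], views$Y[!tr, ])

screen <- select_significant(model$train_correlations,
                             pr_test$correlations,
                             train_n = sum(tr), test_n = sum(!tr),
                             alpha = 0.05, m = 20)
write.table(format(screen, digits = 4), "results/03_cca_screen.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
saveRDS(model, "scratch/sim/cca_model.rds")
write.table(data.frame(subject_id = views$subject_id[!tr],
                       pr_test$variates_x),
            "scratch/sim/cca_test_variates_x.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

n_sig <- sum(screen$significant)
cat(n_sig, "of 20 component pairs significant in both splits",
    sprintf("(corrected alpha %.4f)\n", attr(screen, "alpha_corrected")))
cat("leading train correlations:",
    sprintf("%.3f", model$train_correlations[1:5]), "\n")
cat("leading test correlations: ",
    sprintf("%.3f", pr_test$correlations[1:5]), "\n")
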