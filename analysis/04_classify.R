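#!/usr/bin/env Rscript
# Cross-validated classification of ASD vs NT from the 80-feature vectors:
# the full seven-model roster with randomized hyperparameter search, at
# the leakage-safe subject level. Writes the Table-1-style leaderboard.
# Runtime: roughly 15 minutes on one core at the default search budget.

suppressPackageStartupMessages(library(microstatr))

f <- read.csv("results/features.csv", check.names = FALSE)
ev <- cross_validated_eval(
  f[, feature_names()], f$group, positive = "ASD",
  folds = 10, search_iters = 20, seed = 42,
  unit = "subject", subject = f$subject,
  nan_policy = "impute_median")

utils::write.csv(ev, "results/leaderboard.csv", row.names = FALSE)
cat("cross-validated leaderboard (mean +/- SD over 10 folds, %):\n")
print(data.frame(classifier = ev$classifier,
                 accuracy = sprintf("%.2f (+/-%.2f)", ev$accuracy_mean,
                                    ev$accuracy_sd),
                 sensitivity = sprintf("%.2f", ev$sensitivity_mean),
                 specificity = sprintf("%.2f", ev$specificity_mean),
                 f1 = sprintf("%.2f", ev$f1_mean),
                 auc = sprintf("%.3f", ev$auc)), row.names = FALSE)
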