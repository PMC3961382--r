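#!/usr/bin/env Rscript
# The core experiment: nested 10-fold cross-validation over the
# top-p SNP grid for every ranking algorithm x LD mode x penalty
# combination; final refit on the full training set and evaluation on
# the held-out test set. Emits the per-combination summary table and
# the per-p AUC curves of the best combination.

suppressPackageStartupMessages(library(gwasrisk))

bundle <- read_study_bundle("results/data")

pc <- pipeline_config(
  algorithms = c("trend", "abf", "sis"),
  ld_modes = c("raw", "r2_pruned"),
  alphas = c(0, 0.5, 1),              # ridge, elastic net, lasso
  p_grid = 1:15, folds = 10L, nlambda = 50L,
  seed = 20240115L, output_dir = "results")

res <- run_pipeline(bundle$training, bundle$test, pc,
                    cohort = bundle$cohort)
print(res)
print(res$best)

writeLines(res$best$snps, "results/best_model_snps.txt")
write_risk_model(res$best$models$combined, "results/best_model.json")
write_risk_model(res$best$models$clinical, "results/clinical_model.json")
cat("grid table: results/model_grid.tsv; best model:",
    "results/best_model.json\n")
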