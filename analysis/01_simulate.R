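#!/usr/bin/env Rscript
# Generate the synthetic study: a case-control discovery panel with the
# covariate shifts and modest per-allele effects typical of type 2
# diabetes GWAS, split 9:1 into training and test, plus an independent
# prospective cohort whose hazard follows the true risk score.
# Writes the bundle to results/data/ in the plain-text formats.

suppressPackageStartupMessages(library(gwasrisk))

cfg <- simulation_config(
  n_subjects = 3000L, n_snps = 300L,
  ld_block_spec = list(c(2, 0.99), c(3, 0.85)),
  seed = 20240101L)
scfg <- survival_sim_config(n_subjects = 2116L, seed = 20240108L)

bundle <- make_fixture_study(cfg, scfg, dir = "results/data")

cat("training:", nrow(bundle$training$phenotypes), "subjects (",
    sum(bundle$training$phenotypes$status), "cases )\n")
cat("test:    ", nrow(bundle$test$phenotypes), "subjects\n")
cat("cohort:  ", nrow(bundle$cohort), "subjects,",
    sum(bundle$cohort$event), "events\n")
age_by <- tapply(bundle$training$phenotypes$age,
                 bundle$training$phenotypes$status, mean)
cat("mean age case/control:", round(age_by[["1"]], 1), "/",
    round(age_by[["0"]], 1), "\n")
cat("bundle written to results/data/\n")
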