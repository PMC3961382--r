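# gwasrisk

Construction and prospective validation of risk prediction models for
binary disease outcomes from case-control GWAS data.

Common-disease GWAS yield many associated SNPs whose per-allele odds
ratios are small (roughly 1.05–1.35 for type 2 diabetes), while clinical
covariates such as age, gender and BMI already discriminate strongly.
The practical questions are how many SNPs to carry into a risk model,
how to weight them against the clinical factors, whether interactions
among risk factors add anything, and whether the resulting score
stratifies risk in an independent longitudinal cohort. `gwasrisk`
implements the complete workflow for answering them:

1. **SNP quality control** — call rate ≥ 0.99, Hardy–Weinberg exact
   test (in controls) ≥ 1e-6, MAF ≥ 0.05 — and a Cochran–Armitage trend
   scan with the genomic inflation factor
   λ = median(χ²) / median(χ²₁).
2. **SNP ranking** by three algorithms, each scored so smaller is more
   significant: the trend-test p-value; the asymptotic Bayes factor
   ABF = √((V+W)/V) · exp(−z²/2 · W/(V+W)) under a normal N(0, W)
   prior on the log odds ratio (default W = 0.21², i.e. 95% prior
   belief that the odds ratio is below 1.5); and the sure-independence
   -screening marginal utility (minimized negative log-likelihood of
   the one-SNP logistic model).
3. **LD pruning**: greedy removal of any SNP whose r² with a retained
   higher-ranked SNP strictly exceeds 0.8, from in-sample genotypes or
   an external r² table (with the table's missing-SNP failure mode
   surfaced as a warning).
4. **Penalized logistic models** over top-p SNPs + clinical covariates
   (glmnet; ridge α = 0, elastic net, lasso α = 1; λ by seeded 10-fold
   CV), with the SNP count p chosen by **nested 10-fold
   cross-validation** in which SNPs are re-ranked inside every fold —
   the leakage-free construction — and the final model evaluated once
   on a held-out test set (AUC, DeLong CIs, ROC, Youden operating
   point).
5. **Interaction screening**: all pairwise products of model features,
   1-df likelihood-ratio tests on unpenalized fits, p < 0.05, plus a
   joint LRT and test-set AUC delta for the selected pairs.
6. **Prospective validation**: score a longitudinal cohort without
   refitting, split into three equal-sized risk tertiles, Kaplan–Meier
   curves and the log-rank trend test
   U²/Var(U) with U = Σ c_g(O_g − E_g).

A seeded synthetic-data generator (`simulation_config`,
`make_fixture_study`) reproduces the statistical structure this
pipeline assumes — case/control imbalance, case-control covariate
shifts, a handful of weak causal SNPs, LD proxy pairs, and survival
times whose hazard follows the true score — so every stage is testable
without access to individual-level biobank data.

## Worked example

```r
library(gwasrisk)

# a synthetic study: 2,000 subjects x 300 SNPs, nine causal SNPs with
# odds ratios 1.05-1.35, case-control age/BMI shifts, one r2 = 0.99
# proxy pair
cfg  <- simulation_config(n_subjects = 2000, n_snps = 300,
                          ld_block_spec = list(c(2, 0.99)), seed = 7)
scfg <- survival_sim_config(n_subjects = 2116, seed = 8)
study <- make_fixture_study(cfg, scfg)

qc <- qc_filter(study$training$genotypes, study$training$phenotypes)
scan <- trend_scan(qc$genotypes, study$training$phenotypes)
genomic_inflation(scan$chisq)
#> [1] 1.05

cv <- cv_select_snp_count(qc$genotypes, study$training$phenotypes,
                          algorithm = "abf", ld_mode = "r2_pruned",
                          alpha = 1, p_grid = 1:10, seed = 1, nlambda = 50)
cv$chosen_p
#> [1] 1

ev <- evaluate_final(list(genotypes = qc$genotypes,
                          phenotypes = study$training$phenotypes),
                     study$test, algorithm = "abf", ld_mode = "r2_pruned",
                     alpha = 1, p = cv$chosen_p, seed = 1, nlambda = 50)
print(ev)
#> evaluation_result [abf / r2_pruned / alpha=1.0 / p=1]
#>   AUC clinical-only: 0.8077 (0.7476-0.8678)
#>   AUC combined:      0.8081 (0.7480-0.8683)

val <- compare_clinical_vs_combined(ev$models$clinical,
                                    ev$models$combined, study$cohort)
val$summary
#>      model trend_statistic       trend_p
#> 1 clinical        588.2982 5.875880e-130
#> 2 combined        610.5514 8.488116e-135
```

Reading the output: the genomic inflation factor near 1 says the scan
is not confounded; at this sample size the cross-validated selection
carries a single SNP, and the genetic increment on top of the clinical
covariates is small (AUC 0.8077 → 0.8081) — with odds ratios this
small, the clinical factors dominate and genetics adds a measurable
but modest amount, which is the regime the generator is built to
emulate. In the prospective cohort both scores separate the risk
tertiles decisively, the combined score slightly more so (larger trend
statistic).

The numbered scripts under `analysis/` run the same workflow at a
larger scale (3,000 × 300, full algorithm × LD × penalty grid) and
write every intermediate table — QC report, Manhattan/QQ tables, the
per-combination model grid, interaction scan, KM curves — under
`results/`.

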