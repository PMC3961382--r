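---
title: "Constructing and validating GWAS-based risk prediction models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constructing and validating GWAS-based risk prediction models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gwasrisk)
```

## The problem

Common-disease GWAS panels yield many SNPs with small per-allele effects
(odds ratios roughly 1.05–1.35 for type 2 diabetes). A clinically useful
risk model must decide *which* SNPs to carry, *how* to weight them
alongside much stronger clinical covariates (age, gender, BMI), and
whether the resulting score actually stratifies risk in an independent
longitudinal cohort. `gwasrisk` implements that whole workflow: three
marginal SNP-ranking algorithms, LD-aware pruning, penalized logistic
model construction with nested cross-validated selection of the SNP
count, pairwise interaction screening, and Kaplan–Meier/log-rank-trend
validation, together with a seeded synthetic-data generator so every
stage is testable without individual-level study data.

## Ranking algorithms

All three algorithms score each SNP marginally (no covariate
adjustment, matching the additive single-SNP association model), and in
all three conventions *smaller scores are more significant*:

* **Cochran–Armitage trend test.** The 1-df score statistic with
  additive weights (0, 1, 2); it equals $N r^2$ where $r$ is the
  Pearson correlation between allele count and status. The scan
  (`trend_scan`) is fully vectorized across SNPs and also feeds the
  genomic inflation factor $\lambda = \mathrm{median}(\chi^2)/0.4549$.
* **Asymptotic Bayes factor (ABF).** From the single-SNP logistic MLE
  $\hat\beta$ with standard error $\sqrt V$ and Wald statistic
  $z = \hat\beta/\sqrt V$,
  $\mathrm{ABF} = \sqrt{(V+W)/V}\,\exp\!\big(-\tfrac{z^2}{2}\tfrac{W}{V+W}\big)$,
  the Bayes factor *for the null* under a normal prior $N(0, W)$ on the
  log odds ratio. The default $W = 0.21^2$ encodes 95% prior belief
  that the per-allele odds ratio is below 1.5.
* **Sure independence screening (SIS).** The marginal utility is the
  minimized negative log-likelihood of the two-parameter logistic model
  (intercept + allele count).

The ABF and SIS scans share a Newton solver vectorized across SNPs
(`single_snp_logistic`); it performs closed-form 2×2 updates for every
SNP simultaneously, flags complete separation (|β| > 15) instead of
penalizing, and is verified against `glm` in the test suite. Ties in
any ranking are broken lexicographically by SNP id so reruns are
deterministic.

**LD pruning** (`ld_prune`) walks the ranking from the top and removes
a SNP only when its $r^2$ with an already retained, higher-ranked SNP
*strictly* exceeds the threshold (default 0.8). The LD source is either
the sample itself or an external `(snp_a, snp_b, r2)` table; a SNP
missing from an external table cannot be tested and is retained with a
warning — the realistic failure mode in which a near-perfect proxy pair
($r^2 \approx 0.99$) survives table-based pruning.

## Model construction and selection

Risk models are penalized logistic regressions over the top-$p$ SNPs
plus the three clinical covariates, minimizing
$-\ell(\beta)/n + \lambda\big[(1-\alpha)\|\beta\|_2^2/2 +
\alpha\|\beta\|_1\big]$ via glmnet with internally standardized
features (the cited convention; a `standardize` flag is exposed).
$\alpha = 0$ is ridge, $\alpha = 1$ the lasso, and intermediate values
the elastic net; $\lambda$ is chosen by seeded 10-fold CV minimizing
binomial deviance (CV-AUC selection by flag — deviance is the software
default and the more stable criterion).

`cv_select_snp_count` chooses $p$: in each of 10 outer folds the SNPs
are ranked *on the nine-tenths only* — re-ranking per fold is essential,
since ranking on the full training set leaks the held-out tenth and
inflates the apparent AUC (the package ships a `leakage` switch purely
so tests can demonstrate this) — optionally pruned, fitted at each $p$
in the grid, and scored on the held-out tenth. The chosen $p$ maximizes
the mean held-out AUC; ties go to the smaller $p$ (parsimony, and
cheaper genotyping). Outer folds are stratified by case status to avoid
single-class folds at small $n$. The final model is refit on the
complete training set and evaluated once on the untouched test set
(AUC with DeLong-type placement-variance CIs, the ROC curve, and the
Youden operating point, ties at the maximum resolved to the lower
threshold).

Interaction screening (`pairwise_interaction_scan`) tests every
unordered pair of model features by a 1-df likelihood-ratio test of the
main-effects logistic model against main effects + that one product
term. These LRTs use *unpenalized* maximum-likelihood fits: a penalized
"likelihood ratio" has no $\chi^2_1$ reference, and the classical
nested-model test is what an ANOVA-style comparison means. No
multiplicity correction is applied by default (screening at p < 0.05;
a Bonferroni flag exists). Penalization re-enters only in the
augmentation refit, which also reports the joint (df = number of
pairs) LRT and the test-set AUC change.

## Prospective validation

`score_cohort` applies the fitted linear predictor to a longitudinal
cohort without refitting. Subjects are ranked by score and cut into
three contiguous, equal-sized categories (`tertile_categorize`); sizes
differ by at most one (2,116 subjects → 706/705/705), ties broken by
subject id. Rank-based boundaries rather than score quantiles guarantee
the equal-size property even with heavily tied scores. Kaplan–Meier
curves come from `survival::survfit`; the ordered-category comparison
is the log-rank trend test with scores (1, 2, 3) (configurable;
equally spaced is the default because no other spacing is implied by
the design): $U = \sum_g c_g (O_g - E_g)$ accumulated over event times
with the hypergeometric variance, $U^2/\mathrm{Var}(U) \sim \chi^2_1$.
With two groups this reduces exactly to the standard log-rank test,
which is how it is cross-checked against `survival::survdiff`. Cox
models are deliberately out of scope (the validation design anticipates
crossing hazards).

## The synthetic-data generator

The generator is first-class, tested code; its defaults are the study
conditions every calibration and recovery test runs under:

* **Genotypes** (`generate_genotypes`): per-SNP MAF uniform on
  [0.05, 0.5]; two haplotypes per subject, so Hardy–Weinberg holds.
  LD blocks use a haplotype-copying scheme — each block member copies a
  shared latent allele with probability $t = (r^2)^{1/4}$, giving
  pairwise genotype correlation $t^2 = \sqrt{r^2}$, i.e. $r^2$ as
  specified, while preserving the marginal frequency. This reproduces
  the only LD feature the pipeline consumes (pairwise $r^2$), not
  population-genetic structure.
* **Phenotypes** (`generate_phenotypes`): status is Bernoulli under a
  logit with baseline $\log(4449/2911)$ (the study's 60/40 imbalance),
  nine causal SNPs with odds ratios spread log-evenly over 1.05–1.35,
  optional direct clinical and interaction terms. Age and BMI are then
  *redrawn conditional on the realised status* (case/control means
  65.5/51.6 years and 23.8/23.2 kg/m², SDs 10 and 3 — SDs are not
  reported for the study and are generator conventions), reusing the
  same standard-normal deviates so the seed fully determines the data.
  Drawing covariates conditional on status, rather than generating
  status from covariates, reproduces the regime in which clinical-only
  models already discriminate strongly (AUC ≈ 0.8) and genetics adds a
  small increment. Gender is Bernoulli(0.5) independent of status (no
  gender split is reported).
* **Survival cohorts** (`generate_survival_cohort`): exponential event
  times with rate
  $h_0 \exp\{c\,(\mathrm{score}-\overline{\mathrm{score}})\}$ and
  administrative censoring; defaults $n = 2116$, $h_0 = 0.01$/year,
  $c = 1$ per score unit, censoring at 14 years emulate a ~2,100-person
  community cohort with a modest event rate.

What the generator does **not** emulate: population stratification,
relatedness, genotyping error, imputation uncertainty, haplotype-level
structure, non-proportional or time-varying covariate effects. Tests
passing on these data therefore certify the *procedures* (no leakage,
correct tests, correct estimators, recovery of planted effects at
realistic effect sizes), not performance on any real cohort; in
particular the published AUCs of the motivating study depend on
non-public biobank data and are not reproduction targets.

## Numerical choices and degenerate inputs

* HWE exact test: two-sided summation of conditional heterozygote
  probabilities (recurrence form); compared to a log-gamma enumeration
  oracle in tests. The motivating study's printed HWE and genome-wide
  thresholds are typographically lost; defaults 1e-6 and 5e-8 are the
  conventional values and are configurable. HWE is computed in controls
  only by default, so true associations are not excluded by their
  case-driven HWE distortion.
* Missing genotypes surviving QC are mean-imputed per SNP before model
  fitting (preserves allele frequency); association scans use pairwise
  complete observations instead.
* Zero-variance SNPs: trend statistic 0 with p = 1 and a flag; LD
  $r^2$ against a constant vector is reported as 0 with a warning.
* Train/test split: training receives `round(n(1-f))` subjects
  (7,360 → 6,624/736); unstratified by default, stratification by flag.
* The nested-CV grid defaults to p ∈ 1..30. Analysis drivers and the
  acceptance script run a scaled study (3,000 × 300, grid 1..15,
  λ-path length 50) — sizes chosen so the full grid runs in minutes
  while every qualitative property (leakage-free selection, planted-SNP
  recovery, tertile separation) is preserved.
* KM curves are compared across categories only over their common
  support (up to the earlier of the two groups' last observation);
  beyond it the product-limit estimate is undefined.

## Known limitations

Single-SNP scans are unadjusted for covariates (matching the marginal
association model; adjusted scans would require a different utility
definition). The interaction scan is restricted to the selected model's
features — the full pairwise space over all candidate factors is
combinatorially out of reach and would demand multiplicity control that
the screening design deliberately avoids. Penalized fits rely on
glmnet's convergence at very small λ; the MLE-recovery tolerance in the
tests (1e-3) reflects that. The log-rank trend test assumes independent
censoring.
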