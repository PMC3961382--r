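test_that("configuration validation rejects degenerate inputs", {
  expect_error(simulation_config(maf_range = c(0, 0.3)), "maf_range")
  expect_error(simulation_config(maf_range = c(0.1, 0.6)), "maf_range")
  expect_error(simulation_config(n_snps = 10,
                                 causal_effects = list(index = 11, beta = 1)),
               "causal")
  expect_error(survival_sim_config(baseline_hazard = 0), "positive")
})

test_that("same seed reproduces bit-identical genotypes and phenotypes", {
  cfg <- simulation_config(n_subjects = 50, n_snps = 20, seed = 99)
  expect_identical(generate_genotypes(cfg), generate_genotypes(cfg))
  G <- generate_genotypes(cfg)
  expect_identical(generate_phenotypes(G, cfg), generate_phenotypes(G, cfg))
})

test_that("allele frequencies and HWE are calibrated at fixed MAF", {
  cfg <- simulation_config(n_subjects = 5000, n_snps = 200,
                           maf_range = c(0.3, 0.3), causal_effects = list(),
                           seed = 11)
  G <- generate_genotypes(cfg)
  expect_true(all(G$calls %in% 0:2))
  maf_hat <- colMeans(G$calls) / 2
  expect_gte(mean(abs(maf_hat - 0.3) <= 0.02), 0.95)
  hwe_p <- vapply(seq_len(200), function(j) {
    g <- G$calls[, j]
    hwe_exact_test(sum(g == 0), sum(g == 1), sum(g == 2))
  }, numeric(1))
  # discrete exact p-values are conservative; demand only that they are
  # not concentrated at small values
  expect_lt(mean(hwe_p < 0.05), 0.1)
})

test_that("LD blocks reach their target r-squared", {
  cfg <- simulation_config(n_subjects = 4000, n_snps = 30,
                           ld_block_spec = list(c(3, 0.99), c(2, 0.5)),
                           causal_effects = list(), seed = 21)
  G <- generate_genotypes(cfg)
  r2_block1 <- cor(G$calls[, 1], G$calls[, 2])^2
  r2_block2 <- cor(G$calls[, 4], G$calls[, 5])^2
  r2_off <- cor(G$calls[, 10], G$calls[, 20])^2
  expect_gt(r2_block1, 0.95)
  expect_lt(abs(r2_block2 - 0.5), 0.12)
  expect_lt(r2_off, 0.01)
})

test_that("phenotype generator is calibrated under the null", {
  st <- small_study(n = 5000, m = 5, causal = list(), seed = 31,
                    shift = NULL, baseline = 0)
  se3 <- 3 * sqrt(0.25 / 5000)
  expect_lt(abs(mean(st$P$status) - 0.5), se3)

  cfg <- simulation_config(n_subjects = 200, n_snps = 5,
                           causal_effects = list(),
                           baseline_log_odds = -30, seed = 32)
  G <- generate_genotypes(cfg)
  P <- generate_phenotypes(G, cfg)
  expect_true(all(P$status == 0))
})

test_that("a planted log-odds ratio is recovered by an unpenalized refit", {
  st <- small_study(n = 20000, m = 3,
                    causal = list(index = 2, beta = log(1.35)),
                    seed = 41, shift = NULL, baseline = 0)
  fit <- single_snp_logistic(st$G$calls[, 2, drop = FALSE], st$P$status)
  expect_lt(abs(fit$beta[1] - log(1.35)), 0.05)
})

test_that("case-control covariate shifts appear in the covariates", {
  st <- small_study(n = 4000, m = 5, seed = 51)
  mean_age <- tapply(st$P$age, st$P$status, mean)
  mean_bmi <- tapply(st$P$bmi, st$P$status, mean)
  expect_lt(abs(mean_age[["1"]] - 65.5), 1)
  expect_lt(abs(mean_age[["0"]] - 51.6), 1)
  expect_lt(abs(mean_bmi[["1"]] - 23.8), 0.3)
  expect_lt(abs(mean_bmi[["0"]] - 23.2), 0.3)
})

test_that("survival cohort respects censoring and hazard direction", {
  st <- small_study(n = 300, m = 4, seed = 61)
  model <- risk_model(features = c("age", "gender", "bmi"), intercept = 0,
                      coefficients = c(0.05, 0, 0.1), alpha = NA, lambda = 0)
  cfg0 <- survival_sim_config(n_subjects = 300, censoring_time_max = 0,
                              seed = 1)
  ch0 <- generate_survival_cohort(model, st$G, st$P, cfg0)
  expect_true(all(ch0$event == 0))
  expect_true(all(ch0$time == 0))

  # positive hazard coefficient: mean event time decreases across tertiles
  hits <- 0L
  for (r in 1:100) {
    cfg1 <- survival_sim_config(n_subjects = 300, baseline_hazard = 0.05,
                                score_hazard_coefficient = 1,
                                censoring_time_max = 1e6, seed = r)
    ch <- generate_survival_cohort(model, st$G, st$P, cfg1)
    tert <- tertile_categorize(ch$score, ch$subject_id)
    mt <- tapply(ch$time, tert, mean)
    hits <- hits + (mt[["low"]] > mt[["intermediate"]] &&
                      mt[["intermediate"]] > mt[["high"]])
  }
  expect_gte(hits, 85)
})

test_that("study bundles split 9:1 and round-trip through the files", {
  cfg <- simulation_config(n_subjects = 1000, n_snps = 30, seed = 71)
  scfg <- survival_sim_config(n_subjects = 150, seed = 72)
  dir <- withr::local_tempdir()
  b <- make_fixture_study(cfg, scfg, dir = dir)
  expect_equal(nrow(b$test$phenotypes), 100)
  expect_equal(nrow(b$training$phenotypes), 900)
  b2 <- read_study_bundle(dir)
  expect_equal(b2$training$genotypes$calls, b$training$genotypes$calls)
  expect_equal(b2$test$phenotypes$status, b$test$phenotypes$status)
  expect_equal(b2$cohort$time, b$cohort$time, tolerance = 1e-8)
  expect_equal(b2$oracle_model$coefficients, b$oracle_model$coefficients,
               tolerance = 1e-10)
})
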