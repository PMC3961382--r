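test_that("trend statistic on 2x3 tables: trivial cases and symmetry", {
  even <- rbind(controls = c(10, 10, 10), cases = c(10, 10, 10))
  r <- cochran_armitage_trend(even)
  expect_equal(r$chisq, 0)
  expect_equal(r$p, 1)

  tab <- rbind(c(30, 20, 10), c(10, 20, 30))
  expect_equal(cochran_armitage_trend(tab)$chisq,
               cochran_armitage_trend(tab[2:1, ])$chisq, tolerance = 1e-12)

  degen <- rbind(c(0, 12, 0), c(0, 8, 0))
  expect_true(cochran_armitage_trend(degen)$degenerate)
})

test_that("trend statistic equals N * r^2 on random tables", {
  set.seed(21)
  for (i in 1:300) {
    tab <- matrix(sample(0:50, 6, TRUE), 2)
    if (sum(colSums(tab) > 0) < 2) next
    if (sum(tab[1, ]) == 0 || sum(tab[2, ]) == 0) next
    g <- c(rep(0:2, tab[1, ]), rep(0:2, tab[2, ]))
    y <- rep(0:1, rowSums(tab))
    if (var(g) == 0) next
    expect_equal(cochran_armitage_trend(tab)$chisq,
                 sum(tab) * cor(g, y)^2, tolerance = 1e-10)
  }
})

test_that("ABF closed form: anchor value, limits, and domain errors", {
  W <- 0.21^2
  expect_equal(abf(0, 0.1, W), sqrt((0.01 + W) / 0.01), tolerance = 1e-12)
  # monotone decrease in |z| at fixed V, W; vanishes in the limit
  V <- 0.01
  zs <- seq(0, 40, by = 0.5)
  vals <- abf(zs * sqrt(V), sqrt(V), W)
  expect_true(all(diff(vals) < 0))
  expect_lt(vals[length(vals)], 1e-12)
  expect_error(abf(0.1, 0), "positive")
  expect_error(abf(0.1, 0.1, W = 0), "positive")
})

test_that("ABF equals the quadrature oracle across the parameter range", {
  set.seed(22)
  for (i in 1:200) {
    V <- 10^runif(1, -4, 0)
    z <- runif(1, -6, 6)
    se <- sqrt(V)
    a <- abf(z * se, se)
    q <- abf_quadrature_oracle(z * se, se)
    expect_lt(abs(a - q) / q, 1e-6)
  }
})

test_that("vectorized single-SNP logistic matches glm", {
  set.seed(23)
  n <- 400
  calls <- matrix(rbinom(n * 8, 2, runif(8, 0.1, 0.5)), n, 8, byrow = FALSE)
  y <- rbinom(n, 1, plogis(-0.4 + 0.3 * calls[, 3]))
  fit <- single_snp_logistic(calls, y)
  for (j in 1:8) {
    gl <- glm(y ~ calls[, j], family = binomial())
    expect_equal(fit$beta[j], unname(coef(gl)[2]), tolerance = 1e-6)
    expect_equal(fit$se[j], summary(gl)$coefficients[2, 2],
                 tolerance = 1e-4)
    expect_equal(fit$loglik[j], as.numeric(logLik(gl)), tolerance = 1e-8)
  }
})

test_that("SIS utility: constant SNP reduces to intercept-only deviance", {
  y <- rep(c(0, 1, 1), 20)
  yb <- mean(y)
  expect_equal(sis_marginal_utility(rep(1, 60), y),
               -60 * (yb * log(yb) + (1 - yb) * log(1 - yb)),
               tolerance = 1e-10)
})

test_that("SIS utility matches a generic convex-optimizer oracle", {
  set.seed(24)
  for (i in 1:20) {
    n <- 250
    g <- rbinom(n, 2, runif(1, 0.15, 0.45))
    y <- rbinom(n, 1, plogis(-0.2 + runif(1, -0.5, 0.5) * g))
    nll <- function(par) {
      eta <- par[1] + par[2] * g
      -sum(y * eta - log1p(exp(eta)))
    }
    opt <- optim(c(0, 0), nll, method = "BFGS",
                 control = list(reltol = 1e-14))
    expect_equal(sis_marginal_utility(g, y), opt$value, tolerance = 1e-6)
  }
})

test_that("all three algorithms put a strongly planted SNP first", {
  st <- small_study(n = 5000, m = 50,
                    causal = list(index = 20, beta = log(1.6)),
                    seed = 25, shift = NULL)
  for (alg in c("trend", "abf", "sis")) {
    rk <- rank_snps(st$G, st$P, alg)
    expect_equal(rk$snp[1], "snp0020")
  }
})

test_that("rankings are deterministic with lexicographic tie-breaks", {
  G <- gm_from_calls(cbind(c(0, 1, 2, 0, 1, 2), c(0, 1, 2, 0, 1, 2)))
  P <- pheno_from_y(c(0, 0, 1, 0, 1, 1))
  rk <- rank_snps(G, P, "trend")
  # identical genotype columns -> tied scores -> id order
  expect_equal(rk$snp, c("snp001", "snp002"))
  expect_equal(rk$score[1], rk$score[2])

  single <- rank_snps(gm_from_calls(matrix(c(0, 1, 2, 1, 0, 2), ncol = 1)),
                      P, "abf")
  expect_equal(single$rank, 1L)
})

test_that("r_squared: identity, allele flip, and null calibration", {
  set.seed(26)
  g <- rbinom(5000, 2, 0.3)
  expect_equal(r_squared(g, g), 1)
  expect_equal(r_squared(g, 2 - g), 1)
  h <- rbinom(5000, 2, 0.3)
  expect_lt(r_squared(g, h), 0.01)
  expect_warning(r2c <- r_squared(rep(1, 10), rbinom(10, 2, 0.4)),
                 "constant")
  expect_equal(r2c, 0)
})

test_that("LD pruning is greedy, strict at the threshold, and honest
           about SNPs missing from an external table", {
  rk <- new_ranking_for_test(c("A", "B", "C"))
  tab <- data.frame(snp_a = c("A", "A", "B"), snp_b = c("B", "C", "C"),
                    r2 = c(0.9, 0.1, 0.1))
  pruned <- ld_prune(rk, ld_table = tab)
  expect_equal(pruned$snp, c("A", "C"))

  tab$r2[1] <- 0.8                       # exactly at the threshold: kept
  expect_equal(ld_prune(rk, ld_table = tab)$snp, c("A", "B", "C"))

  # near-perfect proxy pair survives when one member is not in the table
  tab2 <- data.frame(snp_a = "A", snp_b = "C", r2 = 0.1)
  expect_warning(kept <- ld_prune(rk, ld_table = tab2), "absent")
  expect_true(all(c("A", "B") %in% kept$snp))
})

test_that("in-sample pruning leaves no retained pair above threshold", {
  st <- small_study(n = 1500, m = 40, seed = 27,
                    ld = list(c(4, 0.95), c(4, 0.9)), causal = list())
  rk <- rank_snps(st$G, st$P, "trend")
  pruned <- ld_prune(rk, G = st$G, r2_threshold = 0.8)
  calls <- st$G$calls[, pruned$snp, drop = FALSE]
  r2 <- cor(calls)^2
  diag(r2) <- 0
  expect_lte(max(r2), 0.8)
  expect_lt(nrow(pruned), nrow(rk))
})
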