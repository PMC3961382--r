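test_that("feature matrices have the documented shape and order", {
  st <- small_study(n = 40, m = 12, seed = 31)
  snps9 <- st$G$snps$id[1:9]
  X <- build_features(st$G, st$P, snps9)
  expect_equal(ncol(X), 12)                       # 9 genetic + 3 clinical
  expect_equal(colnames(X), c(snps9, "age", "gender", "bmi"))
  expect_equal(unname(attr(X, "provenance")),
               c(rep("genetic", 9), rep("clinical", 3)))

  X0 <- build_features(st$G, st$P)
  expect_equal(colnames(X0), c("age", "gender", "bmi"))

  Xi <- build_features(st$G, st$P, interactions = list(c("age", "gender")))
  expect_equal(colnames(Xi)[4], "age:gender")
  expect_equal(Xi[, 4], Xi[, "age"] * Xi[, "gender"])

  expect_error(build_features(st$G, st$P, "rs_not_here"), "unknown SNP")
  expect_error(build_features(st$G, st$P,
                              interactions = list(c("age", "nope"))),
               "interaction members")
})

test_that("full shrinkage zeroes every slope and leaves logit(ybar)", {
  st <- small_study(n = 300, m = 6, seed = 32)
  X <- build_features(st$G, st$P, st$G$snps$id[1:3])
  m <- fit_penalized_logistic(X, st$P$status, alpha = 1, lambda_grid = 5)
  expect_true(all(m$coefficients == 0))
  expect_equal(m$intercept, qlogis(mean(st$P$status)), tolerance = 1e-6)
  expect_equal(selected_features(m), character(0))
})

test_that("vanishing penalty recovers the unpenalized MLE", {
  st <- small_study(n = 800, m = 6, seed = 33)
  X <- build_features(st$G, st$P, st$G$snps$id[1:3])
  m <- fit_penalized_logistic(X, st$P$status, alpha = 1,
                              lambda_grid = 1e-7)
  gl <- glm(st$P$status ~ X, family = binomial())
  expect_lt(max(abs(c(m$intercept, m$coefficients) - coef(gl))), 1e-3)
})

test_that("ridge keeps every feature; lasso drops a redundant proxy", {
  set.seed(34)
  n <- 1500
  calls <- matrix(rbinom(n * 10, 2, 0.3), n, 10)
  # column 10 is a near-duplicate of column 9 (r2 ~ 0.99)
  flip <- rbinom(n, 1, 0.005)
  calls[, 10] <- ifelse(flip == 1, sample(0:2, n, TRUE), calls[, 9])
  G <- gm_from_calls(calls)
  y <- rbinom(n, 1, plogis(-0.3 + 0.35 * calls[, 9] + 0.3 * calls[, 1]))
  P <- pheno_from_y(y)
  X <- build_features(G, P, G$snps$id)

  ridge <- fit_penalized_logistic(X, y, alpha = 0, seed = 1)
  expect_equal(selected_features(ridge), colnames(X))

  lasso <- fit_penalized_logistic(X, y, alpha = 1, seed = 1)
  sel <- selected_features(lasso)
  genetic_sel <- intersect(sel, G$snps$id)
  expect_lte(length(genetic_sel), 9)
  expect_false(all(c("snp009", "snp010") %in% genetic_sel))
})

test_that("risk predictions follow the logistic arithmetic", {
  m <- risk_model(features = c("f1", "f2"), intercept = -1,
                  coefficients = c(0.5, -0.25), alpha = 1, lambda = 0.1)
  X <- cbind(f1 = c(2, 0, 4), f2 = c(0, 4, 4))
  pr <- predict_risk(m, X)
  expect_equal(pr$linear_predictor, c(-1 + 1, -1 - 1, -1 + 2 - 1))
  expect_equal(pr$probability, plogis(pr$linear_predictor))
  expect_equal(pr$probability[3], 0.5)                   # eta = 0 -> 0.5

  zero <- risk_model("f1", intercept = 0.7, coefficients = 0,
                     alpha = 0, lambda = 1)
  expect_equal(unique(predict_risk(zero, X)$probability), plogis(0.7))
  expect_error(predict_risk(m, X[, 1, drop = FALSE]), "missing")
})

test_that("predictions are invariant to affine rescaling of features", {
  st <- small_study(n = 500, m = 4, seed = 35)
  X <- build_features(st$G, st$P, st$G$snps$id[1:2])
  m1 <- fit_penalized_logistic(X, st$P$status, alpha = 0.5,
                               lambda_grid = 0.05)
  X2 <- X
  X2[, "age"] <- X[, "age"] / 365.25    # years -> centuries-ish rescale
  m2 <- fit_penalized_logistic(X2, st$P$status, alpha = 0.5,
                               lambda_grid = 0.05)
  expect_equal(predict_risk(m2, X2)$probability,
               predict_risk(m1, X)$probability, tolerance = 1e-6)
})

test_that("dropping a zero-coefficient feature leaves predictions intact", {
  m <- risk_model(c("a", "b", "c"), intercept = 0.2,
                  coefficients = c(0.3, 0, -0.1), alpha = 1, lambda = 0.1)
  X <- cbind(a = rnorm(20), b = rnorm(20), c = rnorm(20))
  m_red <- risk_model(c("a", "c"), intercept = 0.2,
                      coefficients = c(0.3, -0.1), alpha = 1, lambda = 0.1)
  expect_equal(predict_risk(m_red, X)$linear_predictor,
               predict_risk(m, X)$linear_predictor)
})

test_that("degenerate fits are refused", {
  X <- cbind(a = rnorm(30), b = rnorm(30))
  expect_error(fit_penalized_logistic(X, rep(1, 30), alpha = 1),
               "both classes")
  expect_error(fit_penalized_logistic(X, rep(0:1, 15), alpha = 2),
               "alpha")
  expect_error(fit_penalized_logistic(X, rep(0:1, 15), alpha = 1,
                                      lambda_grid = numeric(0)),
               "empty")
})
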