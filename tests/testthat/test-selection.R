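test_that("AUC: worked examples and tie convention", {
  expect_equal(auc(c(0.9, 0.8, 0.7, 0.1), c(1, 1, 0, 0)), 1.0)
  expect_equal(auc(c(0.9, 0.4, 0.6, 0.2), c(1, 1, 0, 0)), 0.75)
  expect_equal(auc(rep(0.3, 10), rep(c(0, 1), 5)), 0.5)
  expect_error(auc(1:4, rep(1, 4)), "both classes")
})

test_that("AUC equals exhaustive pair counting on random instances", {
  set.seed(41)
  for (i in 1:100) {
    n <- sample(4:50, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    s <- sample(round(rnorm(n), 1))     # rounded -> plenty of ties
    expect_equal(auc(s, y), auc_pairs_oracle(s, y), tolerance = 1e-12)
  }
})

test_that("DeLong interval agrees with the pROC reference", {
  skip_if_not_installed("pROC")
  set.seed(42)
  for (i in 1:20) {
    n <- 150
    y <- rbinom(n, 1, 0.45)
    if (sum(y) < 2 || sum(1 - y) < 2) next
    s <- rnorm(n) + y
    ours <- auc_ci(s, y)
    ref <- suppressMessages(pROC::ci.auc(y, s, method = "delong"))
    expect_equal(ours$lower, as.numeric(ref[1]), tolerance = 1e-6)
    expect_equal(ours$auc, as.numeric(ref[2]), tolerance = 1e-12)
    expect_equal(ours$upper, as.numeric(ref[3]), tolerance = 1e-6)
  }
})

test_that("DeLong interval has near-nominal coverage and 1/sqrt(n) width", {
  set.seed(43)
  true_auc <- pnorm(1 / sqrt(2))        # binormal, unit shift
  cover <- 0
  reps <- 1000
  for (i in seq_len(reps)) {
    y <- rep(0:1, each = 60)
    s <- rnorm(120) + y
    ci <- auc_ci(s, y)
    cover <- cover + (ci$lower <= true_auc && true_auc <= ci$upper)
  }
  expect_gt(cover / reps, 0.93)
  expect_lt(cover / reps, 0.97)

  widths <- vapply(c(200, 800, 3200), function(n) {
    y <- rep(0:1, each = n / 2)
    s <- rnorm(n) + y
    ci <- auc_ci(s, y)
    ci$upper - ci$lower
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
  expect_lt(widths[3], widths[1])
  expect_gt(widths[1] / widths[3], 2.5)  # ~ sqrt(16) = 4 in expectation
})

test_that("ROC curve integrates back to the AUC and hits the corners", {
  set.seed(44)
  for (i in 1:100) {
    n <- sample(10:60, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    s <- sample(round(rnorm(n), 1))
    roc <- roc_curve(s, y)
    area <- sum(diff(roc$fpr) *
                  (head(roc$sensitivity, -1) + tail(roc$sensitivity, -1)) / 2)
    expect_equal(area, auc(s, y), tolerance = 1e-10)
    expect_equal(roc$fpr[1], 0)
    expect_equal(roc$sensitivity[nrow(roc)], 1)
  }
  perfect <- roc_curve(c(3, 4, 1, 2), c(1, 1, 0, 0))
  expect_true(any(perfect$fpr == 0 & perfect$sensitivity == 1))
})

test_that("operating point maximizes Youden's index", {
  perfect <- roc_curve(c(3, 4, 1, 2), c(1, 1, 0, 0))
  op <- operating_point(perfect)
  expect_equal(op$sensitivity, 1)
  expect_equal(op$specificity, 1)

  set.seed(45)
  y <- rep(0:1, each = 100)
  s <- rnorm(200, mean = y)
  roc <- roc_curve(s, y)
  op <- operating_point(roc)
  brute <- max(vapply(unique(s), function(t) {
    mean(s[y == 1] >= t) + mean(s[y == 0] < t)
  }, numeric(1)))
  expect_equal(op$sensitivity + op$specificity, brute, tolerance = 1e-12)

  flat <- roc_curve(rep(1, 10), rep(0:1, 5))
  opf <- operating_point(flat)
  expect_equal(opf$sensitivity + opf$specificity, 1)
})

test_that("nested CV: single-point grid is returned as chosen", {
  st <- small_study(n = 250, m = 20, seed = 46,
                    causal = list(index = 3, beta = log(1.6)))
  cv <- cv_select_snp_count(st$G, st$P, algorithm = "trend", alpha = 1,
                            p_grid = 5, folds = 4, seed = 1, nlambda = 30)
  expect_equal(cv$chosen_p, 5L)
  expect_true(all(cv$fold_auc >= 0 & cv$fold_auc <= 1, na.rm = TRUE))
  expect_equal(max(cv$mean_auc), cv$mean_auc[match(5, cv$p_grid)])
})

test_that("nested CV is reproducible under a fixed seed", {
  st <- small_study(n = 300, m = 30, seed = 47)
  run <- function() cv_select_snp_count(st$G, st$P, algorithm = "trend",
                                        alpha = 0.5, p_grid = c(2, 4),
                                        folds = 5, seed = 9, nlambda = 20)
  a <- run(); b <- run()
  expect_identical(a$fold_auc, b$fold_auc)
  expect_identical(a$chosen_p, b$chosen_p)
})

test_that("deliberate ranking leakage inflates null-SNP CV AUC", {
  st <- small_study(n = 500, m = 300, causal = list(), seed = 48,
                    shift = NULL, baseline = 0)
  honest <- cv_select_snp_count(st$G, st$P, algorithm = "trend", alpha = 1,
                                p_grid = 10, folds = 5, seed = 2,
                                nlambda = 20)
  leaky <- cv_select_snp_count(st$G, st$P, algorithm = "trend", alpha = 1,
                               p_grid = 10, folds = 5, seed = 2,
                               nlambda = 20, leakage = TRUE)
  expect_gt(max(leaky$mean_auc), max(honest$mean_auc))
})

test_that("final evaluation separates sets and orders the two AUCs", {
  st <- small_study(n = 900, m = 60, seed = 49,
                    causal = list(index = c(5, 25), beta = log(c(1.9, 1.8))))
  sp <- train_test_split(st$G, st$P, 0.2, seed = 3)
  ev <- evaluate_final(sp$training, sp$test, algorithm = "trend",
                       ld_mode = "raw", alpha = 1, p = 4, nlambda = 30)
  expect_gt(ev$auc_combined$auc, ev$auc_clinical$auc)
  expect_true(ev$auc_combined$lower <= ev$auc_combined$auc &&
                ev$auc_combined$auc <= ev$auc_combined$upper)
  expect_error(evaluate_final(sp$training, sp$training, "trend", "raw", 1,
                              p = 2),
               "overlap")
})

test_that("clinical-only AUC does not depend on the ranking algorithm", {
  st <- small_study(n = 600, m = 40, seed = 50)
  sp <- train_test_split(st$G, st$P, 0.2, seed = 4)
  ev_tr <- evaluate_final(sp$training, sp$test, "trend", "raw", 1, p = 3,
                          nlambda = 30)
  ev_ab <- evaluate_final(sp$training, sp$test, "abf", "raw", 1, p = 3,
                          nlambda = 30)
  expect_equal(ev_tr$auc_clinical$auc, ev_ab$auc_clinical$auc,
               tolerance = 1e-12)
})

test_that("repeated splits return one signed difference per split", {
  st <- small_study(n = 400, m = 30, seed = 51,
                    causal = list(index = 2, beta = log(1.8)))
  one <- repeated_split_effect_size(st$G, st$P, n_splits = 1, p = 2,
                                    seed = 7, nlambda = 20)
  expect_length(one$differences, 1)
  expect_equal(one$min, one$max)
  three <- repeated_split_effect_size(st$G, st$P, n_splits = 3, p = 2,
                                      seed = 7, nlambda = 20)
  expect_length(three$differences, 3)
  expect_equal(three$min, min(three$differences))
  expect_equal(three$differences, three$auc_combined - three$auc_clinical)
})
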