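#' Area under the ROC curve
#'
#' Rank-sum (Mann-Whitney) form: the probability that a randomly chosen
#' case outscores a randomly chosen control, ties counted one half.
#'
#' @param scores Numeric risk scores.
#' @param labels 0/1 case status.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) {
    stop("AUC undefined: both classes required", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' DeLong-type confidence interval for the AUC
#'
#' Asymptotic interval from the placement-value variance: with case
#' placements `V10` (fraction of controls each case outscores) and
#' control placements `V01`, `var(AUC) = var(V10)/n1 + var(V01)/n0`.
#' The interval is truncated to `[0, 1]`; a degenerate variance (e.g.
#' perfect separation) collapses it to a point with a flag.
#'
#' @param scores,labels As in [auc()].
#' @param level Confidence level (default 0.95).
#' @return List `auc`, `lower`, `upper`, `se`, `degenerate`.
#' @export
auc_ci <- function(scores, labels, level = 0.95) {
  labels <- as.integer(labels)
  cs <- scores[labels == 1L]; ct <- scores[labels == 0L]
  n1 <- length(cs); n0 <- length(ct)
  if (n1 < 2L || n0 < 2L) {
    stop("need at least two members of each class", call. = FALSE)
  }
  a <- auc(scores, labels)
  plc <- function(x, ref) {
    vapply(x, function(v) mean((v > ref) + 0.5 * (v == ref)), numeric(1))
  }
  v10 <- plc(cs, ct)          # case placements
  v01 <- 1 - plc(ct, cs)      # control placements on the same scale
  se <- sqrt(stats::var(v10) / n1 + stats::var(v01) / n0)
  degenerate <- !is.finite(se) || se == 0
  z <- stats::qnorm(1 - (1 - level) / 2)
  if (degenerate) {
    lo <- hi <- a
  } else {
    lo <- max(0, a - z * se); hi <- min(1, a + z * se)
  }
  list(auc = a, lower = lo, upper = hi, se = se, degenerate = degenerate)
}

#' ROC curve over all distinct thresholds
#'
#' Step curve of `(1 - specificity, sensitivity)` as the decision
#' threshold sweeps the distinct scores; the trapezoidal area under the
#' returned points equals [auc()] including its tie convention.
#'
#' @param scores,labels As in [auc()].
#' @return Data frame `threshold`, `fpr`, `sensitivity`, `specificity`,
#'   ordered by increasing false positive rate; the first row is the
#'   (0,0) corner (threshold `Inf`), the last the (1,1) corner.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes required", call. = FALSE)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & labels == 1L) / n1,
                numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & labels == 0L) / n0,
                numeric(1))
  data.frame(threshold = c(Inf, thr), fpr = c(0, fpr),
             sensitivity = c(0, tpr), specificity = 1 - c(0, fpr))
}

#' Youden operating point of an ROC curve
#'
#' The threshold maximizing sensitivity + specificity; among ties the
#' lowest threshold is reported.
#'
#' @param roc A data frame from [roc_curve()].
#' @return List `threshold`, `sensitivity`, `specificity`.
#' @export
operating_point <- function(roc) {
  if (!nrow(roc)) stop("empty ROC curve", call. = FALSE)
  j <- roc$sensitivity + roc$specificity
  best <- which(j == max(j))
  pick <- best[which.min(roc$threshold[best])]
  list(threshold = roc$threshold[pick],
       sensitivity = roc$sensitivity[pick],
       specificity = roc$specificity[pick])
}

# stratified fold ids (cases and controls dealt separately)
make_folds <- function(y, k, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (s in unique(y)) {
    idx <- which(y == s)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

#' Select the number of top-ranked SNPs by nested cross-validation
#'
#' The core model-selection experiment: for each cross-validation fold,
#' SNPs are ranked on the nine-tenths training part only (no leakage),
#' optionally LD-pruned, the top-`p` SNPs plus the clinical covariates
#' are fed to a penalized logistic fit (with its own internal lambda
#' cross-validation), and the held-out tenth is scored. The chosen `p`
#' maximizes the mean held-out AUC over the grid, ties going to the
#' smaller `p` (parsimony).
#'
#' @param G,P Training-set genotypes and phenotypes.
#' @param algorithm Ranking algorithm (see [rank_snps()]).
#' @param ld_mode `"raw"` or `"r2_pruned"` (greedy pruning at
#'   `r2_threshold` using in-sample LD).
#' @param alpha Elastic-net mixing parameter.
#' @param p_grid Candidate SNP counts (default 1..30).
#' @param folds Number of outer folds (default 10).
#' @param seed Seed controlling fold assignment and inner lambda CV.
#' @param r2_threshold LD pruning threshold.
#' @param lambda_cv_folds,nlambda Inner lambda-search controls.
#' @param leakage For diagnostics only: rank SNPs once on the full
#'   training set, deliberately leaking the held-out fold into the
#'   ranking. Never use for real model selection.
#' @return Object of class `cv_result`: `algorithm`, `ld_mode`, `alpha`,
#'   `p_grid`, `mean_auc` (per p), `fold_auc` (folds x p matrix),
#'   `chosen_p`.
#' @export
cv_select_snp_count <- function(G, P, algorithm = "trend",
                                ld_mode = c("raw", "r2_pruned"),
                                alpha = 1, p_grid = 1:30, folds = 10L,
                                seed = 1L, r2_threshold = 0.8,
                                lambda_cv_folds = 10L, nlambda = 100L,
                                leakage = FALSE) {
  ld_mode <- match.arg(ld_mode)
  if (!length(p_grid)) stop("empty p grid", call. = FALSE)
  check_aligned(G, P)
  fold <- make_folds(P$status, folds, seed)
  p_grid <- sort(unique(as.integer(p_grid)))
  fold_auc <- matrix(NA_real_, folds, length(p_grid),
                     dimnames = list(NULL, paste0("p", p_grid)))

  full_rank <- if (leakage) rank_top(G, P, algorithm, ld_mode, max(p_grid),
                                     r2_threshold) else NULL
  skipped <- 0L
  for (f in seq_len(folds)) {
    tr <- fold != f; ho <- !tr
    if (length(unique(P$status[ho])) < 2L ||
        length(unique(P$status[tr])) < 2L) {
      warning("fold ", f, " has a single class; skipped")
      skipped <- skipped + 1L
      next
    }
    Gtr <- subset_genotypes(G, subjects = which(tr))
    Ptr <- phenotype_table(P[tr, , drop = FALSE])
    Gho <- subset_genotypes(G, subjects = which(ho))
    Pho <- phenotype_table(P[ho, , drop = FALSE])
    top <- if (leakage) full_rank else
      rank_top(Gtr, Ptr, algorithm, ld_mode, max(p_grid), r2_threshold)
    for (k in seq_along(p_grid)) {
      p <- p_grid[k]
      snps <- utils::head(top, p)
      Xtr <- build_features(Gtr, Ptr, snps)
      model <- fit_penalized_logistic(Xtr, Ptr$status, alpha = alpha,
                                      cv_folds = lambda_cv_folds,
                                      seed = seed + f, nlambda = nlambda)
      Xho <- build_features(Gho, Pho, snps)
      pred <- predict_risk(model, Xho)
      fold_auc[f, k] <- auc(pred$linear_predictor, Pho$status)
    }
  }
  if (skipped == folds) stop("every fold was skipped", call. = FALSE)
  mean_auc <- colMeans(fold_auc, na.rm = TRUE)
  chosen <- p_grid[which.max(mean_auc)]  # which.max takes the first tie
  structure(list(algorithm = algorithm, ld_mode = ld_mode, alpha = alpha,
                 p_grid = p_grid, mean_auc = unname(mean_auc),
                 fold_auc = fold_auc, chosen_p = chosen),
            class = "cv_result")
}

# rank and (optionally) prune, returning the top max_p SNP ids
rank_top <- function(G, P, algorithm, ld_mode, max_p, r2_threshold) {
  rk <- rank_snps(G, P, algorithm)
  if (ld_mode == "r2_pruned") {
    # pruning only matters as deep as the grid reaches; restrict for speed
    depth <- min(nrow(rk), max(5L * max_p, 50L))
    rk <- ld_prune(rk[seq_len(depth), , drop = FALSE], G = G,
                   r2_threshold = r2_threshold)
  }
  utils::head(rk$snp, max_p)
}

#' Fit final models on the full training set and evaluate held out
#'
#' Ranks SNPs on the complete training set, fits a clinical-only and a
#' combined (top-`p` SNPs + clinical) penalized model, and evaluates
#' both on the untouched test set, reporting AUCs with DeLong CIs, the
#' ROC curve of the combined model and its Youden operating point.
#'
#' @param training,test Bundles `list(genotypes, phenotypes)` with
#'   disjoint subjects.
#' @param algorithm,ld_mode,alpha,r2_threshold,seed,nlambda As in
#'   [cv_select_snp_count()].
#' @param p Number of SNPs in the combined model.
#' @return Object of class `evaluation_result`: `auc_clinical`,
#'   `auc_combined` (each with CI), `roc`, `operating_point`, `snps`,
#'   `models`.
#' @export
evaluate_final <- function(training, test, algorithm = "trend",
                           ld_mode = c("raw", "r2_pruned"), alpha = 1, p,
                           r2_threshold = 0.8, seed = 1L, nlambda = 100L) {
  ld_mode <- match.arg(ld_mode)
  if (length(intersect(training$phenotypes$subject_id,
                       test$phenotypes$subject_id))) {
    stop("training and test sets overlap", call. = FALSE)
  }
  top <- rank_top(training$genotypes, training$phenotypes, algorithm,
                  ld_mode, p, r2_threshold)
  snps <- utils::head(top, p)

  X_cl <- build_features(training$genotypes, training$phenotypes)
  m_cl <- fit_penalized_logistic(X_cl, training$phenotypes$status,
                                 alpha = alpha, seed = seed,
                                 nlambda = nlambda)
  X_cb <- build_features(training$genotypes, training$phenotypes, snps)
  m_cb <- fit_penalized_logistic(X_cb, training$phenotypes$status,
                                 alpha = alpha, seed = seed,
                                 nlambda = nlambda)

  Xt_cl <- build_features(test$genotypes, test$phenotypes)
  Xt_cb <- build_features(test$genotypes, test$phenotypes, snps)
  s_cl <- predict_risk(m_cl, Xt_cl)$linear_predictor
  s_cb <- predict_risk(m_cb, Xt_cb)$linear_predictor
  y <- test$phenotypes$status

  roc <- roc_curve(s_cb, y)
  structure(list(
    algorithm = algorithm, ld_mode = ld_mode, alpha = alpha, p = p,
    snps = snps,
    auc_clinical = auc_ci(s_cl, y),
    auc_combined = auc_ci(s_cb, y),
    roc = roc,
    operating_point = operating_point(roc),
    models = list(clinical = m_cl, combined = m_cb)
  ), class = "evaluation_result")
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat(sprintf(
    "evaluation_result [%s / %s / alpha=%.1f / p=%d]\n", x$algorithm,
    x$ld_mode, x$alpha, x$p))
  cat(sprintf("  AUC clinical-only: %.4f (%.4f-%.4f)\n",
              x$auc_clinical$auc, x$auc_clinical$lower, x$auc_clinical$upper))
  cat(sprintf("  AUC combined:      %.4f (%.4f-%.4f)\n",
              x$auc_combined$auc, x$auc_combined$lower, x$auc_combined$upper))
  invisible(x)
}

#' Effect-size distribution over repeated random splits
#'
#' Re-splits the full data 9:1 `n_splits` times; for each split, fits
#' the clinical-only and combined models (the SNP count held fixed) and
#' records the signed test-set AUC difference
#' `AUC(combined) - AUC(clinical-only)`.
#'
#' @param G,P Full-panel genotypes and phenotypes.
#' @param n_splits Number of random splits (default 200).
#' @param test_fraction Held-out fraction per split.
#' @param algorithm,ld_mode,alpha,p,nlambda As in [evaluate_final()].
#' @param seed Master seed; split `i` uses `seed + i`.
#' @return List `differences` (length `n_splits`), `min`, `max`,
#'   `auc_clinical`, `auc_combined` (per-split vectors).
#' @export
repeated_split_effect_size <- function(G, P, n_splits = 200L,
                                       test_fraction = 0.1,
                                       algorithm = "trend",
                                       ld_mode = "raw", alpha = 1, p,
                                       seed = 1L, nlambda = 100L) {
  if (n_splits < 1L) stop("n_splits must be >= 1", call. = FALSE)
  d <- a_cl <- a_cb <- numeric(n_splits)
  for (i in seq_len(n_splits)) {
    sp <- train_test_split(G, P, test_fraction, seed = seed + i)
    ev <- evaluate_final(sp$training, sp$test, algorithm, ld_mode, alpha,
                         p = p, seed = seed + i, nlambda = nlambda)
    a_cl[i] <- ev$auc_clinical$auc
    a_cb[i] <- ev$auc_combined$auc
    d[i] <- a_cb[i] - a_cl[i]
  }
  list(differences = d, min = min(d), max = max(d),
       auc_clinical = a_cl, auc_combined = a_cb)
}
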