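#' Likelihood-ratio test between nested logistic models
#'
#' `statistic = 2 * (loglik_alt - loglik_null)`, referred to a
#' chi-squared distribution with `df_diff` degrees of freedom. The
#' alternative must nest the null; a statistic more negative than a
#' small numerical slack indicates a convergence failure and is an
#' error.
#'
#' @param null_loglik,alt_loglik Maximized log-likelihoods.
#' @param df_diff Difference in number of parameters.
#' @return List `statistic`, `df`, `p`.
#' @export
lrt <- function(null_loglik, alt_loglik, df_diff) {
  stat <- 2 * (alt_loglik - null_loglik)
  if (stat < -1e-8) {
    stop("alternative log-likelihood below the null: non-convergence",
         call. = FALSE)
  }
  stat <- max(stat, 0)
  list(statistic = stat, df = df_diff,
       p = stats::pchisq(stat, df = df_diff, lower.tail = FALSE))
}

# unpenalized logistic fit returning the maximized log-likelihood
logistic_loglik <- function(X, y) {
  fit <- suppressWarnings(
    stats::glm.fit(cbind(`(Intercept)` = 1, X), y,
                   family = stats::binomial()))
  list(loglik = -fit$deviance / 2, converged = fit$converged)
}

#' Scan all pairwise interactions among model features
#'
#' For every unordered pair of feature columns, compares the unpenalized
#' main-effects logistic model against the same model plus that single
#' product term by a 1-df likelihood-ratio test (a test of deviation
#' from a multiplicative odds model). Unpenalized maximum-likelihood
#' fits are used so the chi-squared reference is valid. No multiplicity
#' correction is applied by default, mirroring the p < 0.05 screening
#' rule; `bonferroni = TRUE` divides the level by the number of pairs.
#'
#' @param X Feature matrix from [build_features()] (main effects only).
#' @param y 0/1 status vector.
#' @param alpha_level Significance threshold (default 0.05).
#' @param bonferroni Apply a Bonferroni-adjusted threshold.
#' @return Data frame of class `interaction_scan`, one row per pair,
#'   sorted by p-value: `feature_a`, `feature_b`, `class` (`GF-GF`,
#'   `GF-CF`, `CF-CF`), `statistic`, `df`, `p`, `significant`,
#'   `converged`.
#' @export
pairwise_interaction_scan <- function(X, y, alpha_level = 0.05,
                                      bonferroni = FALSE) {
  k <- ncol(X)
  if (k < 2L) stop("need at least two features", call. = FALSE)
  prov <- attr(X, "provenance")
  if (is.null(prov)) {
    prov <- stats::setNames(rep("clinical", k), colnames(X))
  }
  cls <- function(a, b) {
    tag <- function(f) if (prov[[f]] == "genetic") "GF" else "CF"
    paste(sort(c(tag(a), tag(b)), decreasing = TRUE), collapse = "-")
  }
  null_fit <- logistic_loglik(X, y)
  pairs <- utils::combn(colnames(X), 2L)
  n_pairs <- ncol(pairs)
  thr <- if (bonferroni) alpha_level / n_pairs else alpha_level
  res <- lapply(seq_len(n_pairs), function(i) {
    a <- pairs[1L, i]; b <- pairs[2L, i]
    Xa <- cbind(X, X[, a] * X[, b])
    alt <- logistic_loglik(Xa, y)
    ok <- alt$converged && null_fit$converged
    tst <- if (ok) tryCatch(lrt(null_fit$loglik, alt$loglik, 1L),
                            error = function(e) NULL) else NULL
    data.frame(feature_a = a, feature_b = b, class = cls(a, b),
               statistic = if (is.null(tst)) NA_real_ else tst$statistic,
               df = 1L,
               p = if (is.null(tst)) NA_real_ else tst$p,
               converged = !is.null(tst),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$significant <- !is.na(out$p) & out$p < thr
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "alpha_level") <- thr
  class(out) <- c("interaction_scan", "data.frame")
  out
}

#' Refit the risk model with significant interaction terms
#'
#' Appends the product columns of the given pairs to the feature matrix,
#' refits the penalized model, and reports (i) the joint unpenalized
#' likelihood-ratio test of all added pairs against the main-effects
#' model (df = number of pairs) and (ii) the change in test-set AUC.
#'
#' @param training,test Bundles `list(genotypes, phenotypes)`.
#' @param snps SNP ids of the base model's genetic features.
#' @param pairs List of length-2 character vectors (from the scan).
#' @param alpha,seed,nlambda Passed to [fit_penalized_logistic()].
#' @return List `model`, `joint_lrt` (NULL when no pairs), `auc_base`,
#'   `auc_augmented`, `auc_delta`.
#' @export
augment_model_with_interactions <- function(training, test, snps,
                                            pairs, alpha = 1, seed = 1L,
                                            nlambda = 100L) {
  y <- training$phenotypes$status
  X0 <- build_features(training$genotypes, training$phenotypes, snps)
  m0 <- fit_penalized_logistic(X0, y, alpha = alpha, seed = seed,
                               nlambda = nlambda)
  Xt0 <- build_features(test$genotypes, test$phenotypes, snps)
  a0 <- auc(predict_risk(m0, Xt0)$linear_predictor, test$phenotypes$status)

  if (!length(pairs)) {
    return(list(model = m0, joint_lrt = NULL, auc_base = a0,
                auc_augmented = a0, auc_delta = 0))
  }
  X1 <- build_features(training$genotypes, training$phenotypes, snps,
                       interactions = pairs)
  m1 <- fit_penalized_logistic(X1, y, alpha = alpha, seed = seed,
                               nlambda = nlambda)
  joint <- lrt(logistic_loglik(X0, y)$loglik,
               logistic_loglik(X1, y)$loglik, length(pairs))
  Xt1 <- build_features(test$genotypes, test$phenotypes, snps,
                        interactions = pairs)
  a1 <- auc(predict_risk(m1, Xt1)$linear_predictor, test$phenotypes$status)
  list(model = m1, joint_lrt = joint, auc_base = a0, auc_augmented = a1,
       auc_delta = a1 - a0)
}
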