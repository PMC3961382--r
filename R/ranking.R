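#' Cochran-Armitage test for trend on a 2x3 genotype table
#'
#' Score-form 1-df trend test with weights (0,1,2). The statistic equals
#' `N * r^2`, where `r` is the Pearson correlation between the
#' weight-coded genotype and case status.
#'
#' @param counts 2x3 matrix: rows controls/cases, columns genotype 0/1/2.
#' @param weights Genotype scores (default additive `c(0,1,2)`).
#' @return List with `chisq`, `p`, and `degenerate` (TRUE when only one
#'   genotype column is populated, in which case `chisq = 0`, `p = 1`).
#' @export
cochran_armitage_trend <- function(counts, weights = c(0, 1, 2)) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be nonnegative", call. = FALSE)
  N <- sum(counts)
  if (N == 0) stop("empty table", call. = FALSE)
  col_n <- colSums(counts)
  if (sum(col_n > 0) < 2L) {
    return(list(chisq = 0, p = 1, degenerate = TRUE))
  }
  R <- sum(counts[2L, ])                       # cases
  sw <- sum(weights * col_n)
  sww <- sum(weights^2 * col_n)
  swr <- sum(weights * counts[2L, ])
  num <- (N * swr - R * sw)^2
  den <- R * (N - R) * (N * sww - sw^2)
  if (den <= 0) return(list(chisq = 0, p = 1, degenerate = TRUE))
  chisq <- N * num / den                       # = N * r^2
  list(chisq = chisq,
       p = stats::pchisq(chisq, df = 1, lower.tail = FALSE),
       degenerate = FALSE)
}

#' Asymptotic Bayes factor for a single-SNP association
#'
#' Given the MLE `beta_hat` and its standard error from a logistic
#' regression, with `V = se^2` and Wald statistic `z = beta_hat/se`,
#' the asymptotic Bayes factor in favour of the null under a normal
#' `N(0, W)` prior on the log odds ratio is
#' `sqrt((V + W)/V) * exp(-z^2/2 * W/(V + W))`. Smaller values indicate
#' stronger association. The default prior variance `W = 0.21^2`
#' encodes 95% prior belief that the per-allele odds ratio is below 1.5.
#'
#' @param beta_hat Log odds ratio estimate.
#' @param se Standard error (> 0).
#' @param W Prior variance of the log odds ratio.
#' @return The asymptotic Bayes factor (null/alternative).
#' @export
abf <- function(beta_hat, se, W = 0.21^2) {
  if (any(se <= 0)) stop("standard error must be positive", call. = FALSE)
  if (W <= 0) stop("prior variance W must be positive", call. = FALSE)
  V <- se^2
  z <- beta_hat / se
  sqrt((V + W) / V) * exp(-z^2 / 2 * W / (V + W))
}

#' Vectorized single-SNP logistic regressions
#'
#' Fits `status ~ intercept + allele count` independently for every SNP
#' by Newton-Raphson with closed-form 2x2 solves, vectorized across SNPs.
#' Missing calls must already be imputed. Fits that wander beyond
#' |beta| > 15 (complete separation) are stopped and flagged.
#'
#' @param calls n x m genotype matrix (no missing values).
#' @param y 0/1 status vector.
#' @param max_iter,tol Newton iteration controls.
#' @return List of per-SNP vectors: `beta`, `se`, `loglik` (maximized),
#'   `converged`, `separated`.
#' @export
single_snp_logistic <- function(calls, y, max_iter = 30L, tol = 1e-10) {
  if (anyNA(calls)) stop("impute missing calls before fitting", call. = FALSE)
  if (length(unique(y)) < 2L) stop("status must contain both classes",
                                   call. = FALSE)
  n <- length(y)
  m <- ncol(calls)
  a <- rep(stats::qlogis(mean(y)), m)
  b <- numeric(m)
  active <- rep(TRUE, m)
  separated <- rep(FALSE, m)
  for (it in seq_len(max_iter)) {
    if (!any(active)) break
    G <- calls[, active, drop = FALSE]
    eta <- sweep(G * rep(b[active], each = n), 2L, a[active], `+`)
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu)
    r <- y - mu
    S0 <- colSums(w); S1 <- colSums(w * G); S2 <- colSums(w * G * G)
    t0 <- colSums(r); t1 <- colSums(r * G)
    det <- S0 * S2 - S1^2
    det[det <= 0] <- NA_real_
    da <- (S2 * t0 - S1 * t1) / det
    db <- (S0 * t1 - S1 * t0) / det
    da[is.na(da)] <- 0; db[is.na(db)] <- 0
    a[active] <- a[active] + da
    b[active] <- b[active] + db
    sep_now <- abs(b) > 15
    separated <- separated | sep_now
    conv <- rep(FALSE, m)
    conv[active] <- pmax(abs(da), abs(db)) < tol
    active <- active & !conv & !sep_now
  }
  eta <- sweep(calls * rep(b, each = n), 2L, a, `+`)
  mu <- stats::plogis(eta)
  w <- mu * (1 - mu)
  S0 <- colSums(w); S1 <- colSums(w * calls); S2 <- colSums(w * calls^2)
  det <- S0 * S2 - S1^2
  se <- sqrt(ifelse(det > 0, S0 / det, NA_real_))
  loglik <- colSums(y * eta - log1p(exp(eta)))
  list(beta = b, se = se, loglik = loglik,
       converged = !active, separated = separated)
}

#' SIS marginal utility of one SNP
#'
#' The sure-independence-screening marginal utility is the minimized
#' negative log-likelihood of the two-parameter logistic model
#' `status ~ intercept + allele count`; smaller utilities mark more
#' informative SNPs. A constant SNP yields the intercept-only value
#' `n * (-ybar log ybar - (1-ybar) log(1-ybar))`.
#'
#' @param g Allele-count vector (missing values mean-imputed).
#' @param y 0/1 status vector.
#' @return The marginal utility (negative maximized log-likelihood).
#' @export
sis_marginal_utility <- function(g, y) {
  g <- impute_mean_vec(g)
  if (stats::var(g) == 0) {
    yb <- mean(y)
    return(-length(y) * (yb * log(yb) + (1 - yb) * log(1 - yb)))
  }
  fit <- single_snp_logistic(matrix(g, ncol = 1L), y)
  -fit$loglik[1]
}

impute_mean_vec <- function(g) {
  if (anyNA(g)) g[is.na(g)] <- mean(g, na.rm = TRUE)
  g
}

# mean-impute a call matrix column-wise (allele-frequency preserving)
impute_mean <- function(calls) {
  if (!anyNA(calls)) return(calls)
  mns <- colMeans(calls, na.rm = TRUE)
  idx <- which(is.na(calls), arr.ind = TRUE)
  calls[idx] <- mns[idx[, 2L]]
  calls
}

#' ABF scan over a genotype panel
#'
#' Single-SNP logistic fit per SNP, then the asymptotic Bayes factor of
#' each fitted log odds ratio. Separated (non-convergent) fits receive
#' the worst possible score and are flagged.
#'
#' @param G Post-QC [genotype_matrix()].
#' @param P Aligned [phenotype_table()].
#' @param W Prior variance of the log odds ratio.
#' @return A `snp_ranking` (see [rank_snps()]).
#' @export
abf_scan <- function(G, P, W = 0.21^2) {
  check_aligned(G, P)
  calls <- impute_mean(G$calls)
  fit <- single_snp_logistic(calls, P$status)
  score <- ifelse(fit$separated | is.na(fit$se), Inf,
                  abf(fit$beta, fit$se, W))
  new_ranking(G$snps$id, score, algorithm = "abf",
              flagged = fit$separated | is.na(fit$se))
}

#' Rank SNPs by one of the three detection algorithms
#'
#' `"trend"` ranks by the Cochran-Armitage trend p-value, `"abf"` by the
#' asymptotic Bayes factor, `"sis"` by the SIS marginal utility. All
#' three score conventions place smaller values first; ties are broken
#' lexicographically by SNP id for deterministic reruns.
#'
#' @param G Post-QC [genotype_matrix()].
#' @param P Aligned [phenotype_table()].
#' @param algorithm One of `"trend"`, `"abf"`, `"sis"`.
#' @param W ABF prior variance (ignored by the other algorithms).
#' @return A `snp_ranking`: data frame `rank`, `snp`, `score`,
#'   `algorithm`, `flagged`, sorted most significant first.
#' @export
rank_snps <- function(G, P, algorithm = c("trend", "abf", "sis"),
                      W = 0.21^2) {
  algorithm <- match.arg(algorithm)
  check_aligned(G, P)
  if (algorithm == "trend") {
    sc <- trend_scan(G, P)
    return(new_ranking(sc$snp, sc$p, "trend", flagged = sc$degenerate))
  }
  if (algorithm == "abf") return(abf_scan(G, P, W))
  calls <- impute_mean(G$calls)
  const <- apply(calls, 2L, stats::var) == 0
  fit <- single_snp_logistic(calls, P$status)
  yb <- mean(P$status)
  l0 <- -length(P$status) * (yb * log(yb) + (1 - yb) * log(1 - yb))
  score <- ifelse(const, l0, -fit$loglik)
  new_ranking(G$snps$id, score, "sis", flagged = fit$separated | const)
}

new_ranking <- function(ids, score, algorithm, flagged = FALSE,
                        ld_pruned = FALSE, r2_threshold = NA_real_) {
  ord <- order(score, ids)
  out <- data.frame(rank = seq_along(ids), snp = ids[ord],
                    score = score[ord], algorithm = algorithm,
                    flagged = rep_len(flagged, length(ids))[ord],
                    stringsAsFactors = FALSE)
  attr(out, "ld_pruned") <- ld_pruned
  attr(out, "r2_threshold") <- r2_threshold
  class(out) <- c("snp_ranking", "data.frame")
  out
}

#' Pairwise linkage-disequilibrium r-squared of two SNPs
#'
#' Squared Pearson correlation of the additive allele counts (the
#' composite-genotype LD measure). A constant vector gives `r^2 = 0`
#' with a warning, since LD is undefined there.
#'
#' @param g_a,g_b Allele-count vectors.
#' @return r-squared in `[0, 1]`.
#' @export
r_squared <- function(g_a, g_b) {
  ok <- stats::complete.cases(g_a, g_b)
  if (stats::var(g_a[ok]) == 0 || stats::var(g_b[ok]) == 0) {
    warning("constant genotype vector: r-squared undefined, returning 0")
    return(0)
  }
  stats::cor(g_a[ok], g_b[ok])^2
}

#' Greedy LD pruning of a SNP ranking
#'
#' Scans the ranking from most to least significant and removes any SNP
#' whose r-squared with an already retained higher-ranked SNP strictly
#' exceeds the threshold (a pair at exactly the threshold is kept). The
#' LD source is either the genotype panel itself (in-sample r-squared)
#' or an external lookup table `(snp_a, snp_b, r2)`; a SNP absent from
#' the external table cannot be tested and is retained with a warning —
#' the known failure mode of table-based pruning, where a near-perfect
#' proxy pair survives because one member is missing from the table.
#'
#' @param ranking A `snp_ranking`.
#' @param G Optional [genotype_matrix()] providing in-sample LD.
#' @param ld_table Optional data frame `snp_a`, `snp_b`, `r2`.
#' @param r2_threshold Pruning threshold (strict `>`), default 0.8.
#' @return The pruned `snp_ranking` (original order preserved, ranks
#'   renumbered).
#' @export
ld_prune <- function(ranking, G = NULL, ld_table = NULL, r2_threshold = 0.8) {
  if (is.null(G) && is.null(ld_table)) {
    stop("supply a genotype panel or an external LD table", call. = FALSE)
  }
  ids <- ranking$snp
  use_table <- !is.null(ld_table)
  if (use_table) {
    key <- function(a, b) paste(pmin(a, b), pmax(a, b))
    lut <- stats::setNames(ld_table$r2, key(ld_table$snp_a, ld_table$snp_b))
    in_table <- unique(c(ld_table$snp_a, ld_table$snp_b))
  } else {
    calls <- impute_mean(subset_genotypes(G, snps = ids)$calls)
  }
  keep <- logical(length(ids))
  kept <- character(0)
  for (k in seq_along(ids)) {
    id <- ids[k]
    if (use_table && !(id %in% in_table)) {
      warning("SNP ", id, " absent from the LD table; retained unpruned")
      keep[k] <- TRUE; kept <- c(kept, id); next
    }
    r2s <- if (!length(kept)) numeric(0) else if (use_table) {
      v <- lut[key(id, kept)]
      v[is.na(v)] <- 0
      v
    } else {
      g <- calls[, id]
      if (stats::var(g) == 0) 0 else
        suppressWarnings(stats::cor(g, calls[, kept, drop = FALSE])^2)
    }
    if (!length(r2s) || all(r2s <= r2_threshold, na.rm = TRUE)) {
      keep[k] <- TRUE; kept <- c(kept, id)
    }
  }
  out <- ranking[keep, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "ld_pruned") <- TRUE
  attr(out, "r2_threshold") <- r2_threshold
  class(out) <- c("snp_ranking", "data.frame")
  out
}

#' Write a ranking as TSV
#' @param ranking A `snp_ranking`.
#' @param path Output file.
#' @export
write_ranking <- function(ranking, path) {
  utils::write.table(ranking, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
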