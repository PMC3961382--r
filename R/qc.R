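#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact test conditioning on the observed allele counts: the
#' p-value sums the probabilities of all heterozygote counts whose
#' conditional probability does not exceed that of the observed count.
#' The conditional distribution is evaluated by the standard recurrence
#' over heterozygote counts of matching parity.
#'
#' @param n_AA,n_AB,n_BB Genotype counts.
#' @return Exact p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_AA, n_AB, n_BB) {
  if (any(c(n_AA, n_AB, n_BB) < 0)) stop("negative counts", call. = FALSE)
  n <- n_AA + n_AB + n_BB
  if (n == 0) stop("all-zero genotype table", call. = FALSE)
  n_a <- 2L * n_AA + n_AB            # minor-allele copies (either allele works)
  if (n_a > n) n_a <- 2L * n - n_a   # symmetry: use the rarer allele
  if (n_a == 0L) return(1)

  hets <- seq(n_a %% 2L, n_a, by = 2L)
  probs <- numeric(length(hets))
  # start at the smallest feasible het count, build up by recurrence:
  # P(h+2)/P(h) = 4*nAA(h)*nBB(h) / ((h+2)*(h+1))
  lp <- 0
  lps <- numeric(length(hets))
  for (k in seq_along(hets)) {
    lps[k] <- lp
    h <- hets[k]
    if (k < length(hets)) {
      naa <- (n_a - h) / 2
      nbb <- (2 * n - n_a - h) / 2
      lp <- lp + log(4 * naa * nbb) - log((h + 2) * (h + 1))
    }
  }
  probs <- exp(lps - max(lps))
  probs <- probs / sum(probs)
  obs <- match(n_AB, hets)
  if (is.na(obs)) stop("heterozygote count inconsistent with allele count",
                       call. = FALSE)
  min(1, sum(probs[probs <= probs[obs] * (1 + 1e-12)]))
}

# vectorized per-SNP summary used by QC and the scans
snp_counts <- function(calls) {
  nAA <- colSums(calls == 0L, na.rm = TRUE)
  nAB <- colSums(calls == 1L, na.rm = TRUE)
  nBB <- colSums(calls == 2L, na.rm = TRUE)
  n_obs <- nAA + nAB + nBB
  af <- ifelse(n_obs > 0, (2 * nBB + nAB) / (2 * n_obs), NA_real_)
  list(nAA = nAA, nAB = nAB, nBB = nBB, n_obs = n_obs,
       maf = pmin(af, 1 - af))
}

#' SNP-level quality control
#'
#' Retains SNPs with call rate at or above `call_rate_min`, exact
#' Hardy-Weinberg p-value (computed in controls by default) at or above
#' `hwe_p_min`, and minor allele frequency at or above `maf_min`. The
#' defaults mirror stringent GWAS practice: call rate 0.99, MAF 0.05,
#' HWE 1e-6.
#'
#' @param G A [genotype_matrix()].
#' @param P A [phenotype_table()] aligned with `G`.
#' @param call_rate_min,hwe_p_min,maf_min Thresholds.
#' @param hwe_in_controls Compute the HWE test in controls only
#'   (default), avoiding the exclusion of genuinely associated SNPs.
#' @return List with `genotypes` (the filtered matrix) and `report`
#'   (class `qc_report`): per-SNP call rate, HWE p, MAF, pass flags and
#'   the count passing.
#' @export
qc_filter <- function(G, P, call_rate_min = 0.99, hwe_p_min = 1e-6,
                      maf_min = 0.05, hwe_in_controls = TRUE) {
  check_aligned(G, P)
  cc <- snp_counts(G$calls)
  call_rate <- cc$n_obs / nrow(G$calls)

  hwe_calls <- if (hwe_in_controls) {
    G$calls[P$status == 0L, , drop = FALSE]
  } else G$calls
  hc <- snp_counts(hwe_calls)
  hwe_p <- vapply(seq_len(ncol(G$calls)), function(j) {
    if (hc$n_obs[j] == 0L) return(NA_real_)
    hwe_exact_test(hc$nAA[j], hc$nAB[j], hc$nBB[j])
  }, numeric(1))

  pass_call <- call_rate >= call_rate_min
  pass_hwe <- !is.na(hwe_p) & hwe_p >= hwe_p_min
  pass_maf <- !is.na(cc$maf) & cc$maf >= maf_min
  pass <- pass_call & pass_hwe & pass_maf

  report <- data.frame(snp = G$snps$id, call_rate = call_rate,
                       hwe_p = hwe_p, maf = cc$maf,
                       pass_call_rate = pass_call, pass_hwe = pass_hwe,
                       pass_maf = pass_maf, pass = pass,
                       stringsAsFactors = FALSE)
  attr(report, "n_pass") <- sum(pass)
  class(report) <- c("qc_report", "data.frame")
  if (!any(pass)) warning("no SNPs passed quality control")
  list(genotypes = subset_genotypes(G, snps = which(pass)), report = report)
}

#' Genome-wide Cochran-Armitage trend scan
#'
#' One trend test per SNP against case-control status, emitting a
#' plot-ready table for Manhattan and QQ plots. Missing calls are
#' dropped per SNP (pairwise complete). Zero-variance SNPs are recorded
#' with statistic 0, p = 1 and `degenerate = TRUE`.
#'
#' @param G Post-QC [genotype_matrix()].
#' @param P Aligned [phenotype_table()].
#' @return Data frame: `snp`, `chromosome`, `position`, `chisq`, `p`,
#'   `expected_p` (uniform quantiles by rank, for QQ plots),
#'   `degenerate`.
#' @export
trend_scan <- function(G, P) {
  check_aligned(G, P)
  y <- P$status
  calls <- G$calls
  M <- !is.na(calls)
  X <- calls; X[!M] <- 0
  n_j <- colSums(M)
  sy <- colSums(M * y)
  sx <- colSums(X)
  sxx <- colSums(X * X)
  sxy <- colSums(X * y)
  # N * r^2, the score form of the 1-df trend test
  cov_xy <- sxy - sx * sy / n_j
  var_x <- sxx - sx^2 / n_j
  var_y <- sy - sy^2 / n_j
  degen <- var_x <= 0 | var_y <= 0
  chisq <- ifelse(degen, 0, n_j * cov_xy^2 / (var_x * var_y))
  p <- ifelse(degen, 1, stats::pchisq(chisq, df = 1, lower.tail = FALSE))
  out <- data.frame(snp = G$snps$id, chromosome = G$snps$chromosome,
                    position = G$snps$position, chisq = chisq, p = p,
                    degenerate = degen, stringsAsFactors = FALSE)
  out$expected_p <- (rank(out$p, ties.method = "first") - 0.5) / nrow(out)
  out
}

#' Genomic inflation factor
#'
#' `lambda = median(chisq) / qchisq(0.5, 1)`; values near 1 indicate no
#' systematic confounding of the association scan.
#'
#' @param chisq Vector of 1-df association statistics.
#' @return The inflation factor lambda.
#' @export
genomic_inflation <- function(chisq) {
  if (!length(chisq)) stop("no statistics supplied", call. = FALSE)
  stats::median(chisq) / stats::qchisq(0.5, df = 1)
}

#' Split a study into training and test sets
#'
#' Seeded random partition; the training set receives `round(n*(1-f))`
#' subjects and the test set the remainder, so a 7,360-subject panel at
#' the default 0.1 splits 6,624 / 736. Optionally stratified by case
#' status.
#'
#' @param G A [genotype_matrix()].
#' @param P Aligned [phenotype_table()].
#' @param test_fraction Held-out fraction in (0, 1).
#' @param seed Integer seed.
#' @param stratify Stratify the draw by case status (off by default).
#' @return List with `training` and `test`, each
#'   `list(genotypes, phenotypes)`.
#' @export
train_test_split <- function(G, P, test_fraction = 0.1, seed = 1L,
                             stratify = FALSE) {
  check_aligned(G, P)
  if (test_fraction <= 0 || test_fraction >= 1) {
    stop("test_fraction must be in (0,1)", call. = FALSE)
  }
  n <- length(G$subjects)
  n_train <- round(n * (1 - test_fraction))
  if (n_train < 1L || n_train > n - 1L) {
    stop("sample too small to populate both partitions", call. = FALSE)
  }
  set.seed(seed)
  if (stratify) {
    idx_tr <- integer(0)
    for (s in c(0L, 1L)) {
      idx_s <- which(P$status == s)
      k <- round(length(idx_s) * (1 - test_fraction))
      idx_tr <- c(idx_tr, sample(idx_s, k))
    }
    train_idx <- sort(idx_tr)
  } else {
    train_idx <- sort(sample.int(n, n_train))
  }
  test_idx <- setdiff(seq_len(n), train_idx)
  take <- function(idx) list(
    genotypes = subset_genotypes(G, subjects = idx),
    phenotypes = phenotype_table(P[idx, , drop = FALSE]))
  list(training = take(train_idx), test = take(test_idx))
}
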