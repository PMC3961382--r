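# Shared fixtures built in code; everything is seeded and tiny.

# small case-control panel with a configurable causal architecture
small_study <- function(n = 600, m = 100, causal = list(), seed = 1,
                        ld = list(), shift = default_covariate_shift(),
                        baseline = 0) {
  cfg <- simulation_config(
    n_subjects = n, n_snps = m,
    causal_effects = causal, ld_block_spec = ld,
    baseline_log_odds = baseline,
    case_control_covariate_shift = shift,
    seed = seed)
  G <- generate_genotypes(cfg)
  P <- generate_phenotypes(G, cfg)
  list(G = G, P = P, cfg = cfg)
}

# genotype matrix straight from a call matrix (ids auto-generated)
gm_from_calls <- function(calls) {
  calls <- as.matrix(calls)
  genotype_matrix(
    calls,
    subjects = sprintf("S%03d", seq_len(nrow(calls))),
    snps = data.frame(id = sprintf("snp%03d", seq_len(ncol(calls))),
                      chromosome = 1L, position = seq_len(ncol(calls)),
                      ref = "A", alt = "B", stringsAsFactors = FALSE))
}

pheno_from_y <- function(y, seed = 1) {
  set.seed(seed)
  phenotype_table(data.frame(
    subject_id = sprintf("S%03d", seq_along(y)),
    status = as.integer(y),
    age = rnorm(length(y), 55, 8),
    gender = rbinom(length(y), 1, 0.5),
    bmi = rnorm(length(y), 23, 2.5)))
}

# independent full-enumeration HWE oracle (log-gamma form, no recurrence)
hwe_enum_oracle <- function(n_AA, n_AB, n_BB) {
  n <- n_AA + n_AB + n_BB
  na <- 2 * n_AA + n_AB
  nb <- 2 * n - na
  m <- min(na, nb)
  if (m == 0) return(1)
  hets <- seq(m %% 2, m, by = 2)
  lp <- vapply(hets, function(h) {
    naa <- (na - h) / 2
    nbb <- (nb - h) / 2
    lgamma(n + 1) - lgamma(naa + 1) - lgamma(h + 1) - lgamma(nbb + 1) +
      h * log(2) + lgamma(na + 1) + lgamma(nb + 1) - lgamma(2 * n + 1)
  }, numeric(1))
  p <- exp(lp - max(lp))
  p <- p / sum(p)
  obs <- match(n_AB, hets)
  sum(p[p <= p[obs] * (1 + 1e-12)])
}

# ABF oracle: numerical integration of the marginal likelihood under the
# normal prior, never the closed form
abf_quadrature_oracle <- function(beta_hat, se, W = 0.21^2) {
  V <- se^2
  num <- dnorm(beta_hat, 0, sqrt(V))
  den <- integrate(function(b) dnorm(beta_hat, b, sqrt(V)) *
                     dnorm(b, 0, sqrt(W)),
                   -Inf, Inf, rel.tol = 1e-12)$value
  num / den
}

# hand-built ranking object (most significant first)
new_ranking_for_test <- function(ids, scores = seq_along(ids)) {
  out <- data.frame(rank = seq_along(ids), snp = ids, score = scores,
                    algorithm = "trend", flagged = FALSE,
                    stringsAsFactors = FALSE)
  class(out) <- c("snp_ranking", "data.frame")
  out
}

# exhaustive pair-counting AUC oracle
auc_pairs_oracle <- function(scores, labels) {
  cs <- scores[labels == 1]
  ct <- scores[labels == 0]
  tot <- 0
  for (a in cs) for (b in ct) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(cs) * length(ct))
}
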