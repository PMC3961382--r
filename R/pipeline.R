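#' Pipeline configuration
#'
#' Declarative description of a full model-construction run: the
#' experiment grid (ranking algorithms x LD modes x penalty mixings),
#' QC thresholds, the SNP-count grid, fold counts and one master seed
#' from which every stochastic stage derives its own.
#'
#' @param algorithms Ranking algorithms to try.
#' @param ld_modes LD handling modes.
#' @param alphas Elastic-net mixing parameters (1 = lasso, 0 = ridge).
#' @param p_grid Candidate SNP counts.
#' @param folds Outer cross-validation folds.
#' @param call_rate_min,hwe_p_min,maf_min QC thresholds.
#' @param r2_threshold LD pruning threshold.
#' @param interaction_alpha Interaction-scan significance level.
#' @param nlambda Inner lambda-path length.
#' @param seed Master seed.
#' @param output_dir Optional directory for intermediate tables.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(algorithms = c("trend", "abf", "sis"),
                            ld_modes = c("raw", "r2_pruned"),
                            alphas = c(0, 0.5, 1),
                            p_grid = 1:30, folds = 10L,
                            call_rate_min = 0.99, hwe_p_min = 1e-6,
                            maf_min = 0.05, r2_threshold = 0.8,
                            interaction_alpha = 0.05, nlambda = 100L,
                            seed = 1L, output_dir = NULL) {
  if (!length(algorithms)) stop("empty algorithm list", call. = FALSE)
  if (!all(algorithms %in% c("trend", "abf", "sis"))) {
    stop("unknown ranking algorithm", call. = FALSE)
  }
  if (!all(ld_modes %in% c("raw", "r2_pruned"))) {
    stop("unknown LD mode", call. = FALSE)
  }
  if (!length(alphas) || any(alphas < 0 | alphas > 1)) {
    stop("alphas must lie in [0,1]", call. = FALSE)
  }
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full model-construction and validation workflow
#'
#' QC -> per-combination nested-CV SNP-count selection over the whole
#' grid -> final refit and held-out evaluation -> interaction scan and
#' augmentation for the best combination -> optional prospective
#' validation. Every stage derives its seed from the master seed, so a
#' rerun with the same configuration and data is numerically identical.
#'
#' @param training,test Bundles `list(genotypes, phenotypes)`.
#' @param config A [pipeline_config()].
#' @param cohort Optional `survival_cohort` for prospective validation.
#' @return Object of class `pipeline_result`: `qc_report`,
#'   `inflation`, `grid` (one row per combination, Table-style:
#'   algorithm, ld_mode, alpha, chosen_p, AUCs with CIs), `best`
#'   (its `evaluation_result`), `interactions` (scan + augmentation),
#'   `validation` (when a cohort is given), `config`.
#' @export
run_pipeline <- function(training, test, config = pipeline_config(),
                         cohort = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$output_dir
  emit <- function(obj, name) {
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      utils::write.table(obj, file.path(out_dir, name), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
  }

  qc <- qc_filter(training$genotypes, training$phenotypes,
                  call_rate_min = config$call_rate_min,
                  hwe_p_min = config$hwe_p_min, maf_min = config$maf_min)
  Gq <- qc$genotypes
  P <- training$phenotypes
  emit(qc$report, "qc_report.tsv")

  scan <- trend_scan(Gq, P)
  infl <- genomic_inflation(scan$chisq)
  emit(scan, "trend_scan.tsv")

  grid <- expand.grid(algorithm = config$algorithms,
                      ld_mode = config$ld_modes, alpha = config$alphas,
                      stringsAsFactors = FALSE)
  rows <- vector("list", nrow(grid))
  evals <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    gi <- grid[i, ]
    cv <- cv_select_snp_count(Gq, P, algorithm = gi$algorithm,
                              ld_mode = gi$ld_mode, alpha = gi$alpha,
                              p_grid = config$p_grid,
                              folds = config$folds,
                              seed = config$seed + i,
                              r2_threshold = config$r2_threshold,
                              nlambda = config$nlambda)
    test_qc <- list(genotypes = subset_genotypes(test$genotypes,
                                                 snps = Gq$snps$id),
                    phenotypes = test$phenotypes)
    ev <- evaluate_final(list(genotypes = Gq, phenotypes = P), test_qc,
                         algorithm = gi$algorithm, ld_mode = gi$ld_mode,
                         alpha = gi$alpha, p = cv$chosen_p,
                         r2_threshold = config$r2_threshold,
                         seed = config$seed + i, nlambda = config$nlambda)
    evals[[i]] <- ev
    rows[[i]] <- data.frame(
      algorithm = gi$algorithm, ld_mode = gi$ld_mode, alpha = gi$alpha,
      chosen_p = cv$chosen_p, cv_mean_auc = max(cv$mean_auc),
      auc_clinical = ev$auc_clinical$auc,
      clinical_ci_lower = ev$auc_clinical$lower,
      clinical_ci_upper = ev$auc_clinical$upper,
      auc_combined = ev$auc_combined$auc,
      combined_ci_lower = ev$auc_combined$lower,
      combined_ci_upper = ev$auc_combined$upper,
      stringsAsFactors = FALSE)
  }
  grid_tab <- do.call(rbind, rows)
  emit(grid_tab, "model_grid.tsv")

  best_i <- which.max(grid_tab$auc_combined)
  best <- evals[[best_i]]

  Xb <- build_features(Gq, P, best$snps)
  scan_ia <- pairwise_interaction_scan(Xb, P$status,
                                       alpha_level = config$interaction_alpha)
  emit(scan_ia, "interaction_scan.tsv")
  sig_pairs <- lapply(which(scan_ia$significant), function(r) {
    c(scan_ia$feature_a[r], scan_ia$feature_b[r])
  })
  test_qc <- list(genotypes = subset_genotypes(test$genotypes,
                                               snps = Gq$snps$id),
                  phenotypes = test$phenotypes)
  aug <- augment_model_with_interactions(
    list(genotypes = Gq, phenotypes = P), test_qc, best$snps, sig_pairs,
    alpha = best$alpha, seed = config$seed, nlambda = config$nlambda)

  validation <- NULL
  if (!is.null(cohort)) {
    validation <- compare_clinical_vs_combined(
      best$models$clinical, best$models$combined, cohort)
    emit(validation$clinical$km, "km_clinical.tsv")
    emit(validation$combined$km, "km_combined.tsv")
    emit(validation$summary, "validation_summary.tsv")
  }

  structure(list(qc_report = qc$report, inflation = infl,
                 scan = scan, grid = grid_tab, best = best,
                 interactions = list(scan = scan_ia, augmented = aug),
                 validation = validation, config = config),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("pipeline_result: %d grid combinations, inflation %.3f\n",
              nrow(x$grid), x$inflation))
  cat(sprintf("  best: %s / %s / alpha=%.1f, p=%d, AUC %.4f\n",
              x$best$algorithm, x$best$ld_mode, x$best$alpha, x$best$p,
              x$best$auc_combined$auc))
  if (!is.null(x$validation)) {
    cat(sprintf("  prospective trend p: clinical %.3g, combined %.3g\n",
                x$validation$summary$trend_p[1],
                x$validation$summary$trend_p[2]))
  }
  invisible(x)
}
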