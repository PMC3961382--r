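#' Genotype matrix container
#'
#' Additive allele counts (0/1/2, `NA` for missing) for n subjects by
#' m SNPs, with per-SNP metadata. Columns of `calls` are named by SNP id
#' and rows by subject id.
#'
#' @param calls Integer matrix, n x m, values in {0,1,2,NA}.
#' @param subjects Character vector of subject ids (length n).
#' @param snps Data frame with columns `id`, `chromosome`, `position`,
#'   `ref`, `alt`; `id` must be unique.
#' @return Object of class `genotype_matrix`: a list with elements
#'   `calls`, `subjects`, `snps`.
#' @export
genotype_matrix <- function(calls, subjects, snps) {
  calls <- as.matrix(calls)
  if (nrow(calls) != length(subjects)) {
    stop("subject ids do not match the call matrix rows", call. = FALSE)
  }
  if (ncol(calls) != nrow(snps)) {
    stop("SNP metadata does not match the call matrix columns", call. = FALSE)
  }
  if (anyDuplicated(snps$id)) stop("SNP ids must be unique", call. = FALSE)
  bad <- calls[!is.na(calls)]
  if (length(bad) && (any(bad < 0) || any(bad > 2))) {
    stop("genotype calls must be 0, 1, 2 or NA", call. = FALSE)
  }
  dimnames(calls) <- list(subjects, snps$id)
  structure(list(calls = calls, subjects = as.character(subjects),
                 snps = as.data.frame(snps)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d subjects x %d SNPs (%.2f%% missing)\n",
              nrow(x$calls), ncol(x$calls),
              100 * mean(is.na(x$calls))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

# subset helper used throughout the pipeline
subset_genotypes <- function(G, subjects = NULL, snps = NULL) {
  i <- if (is.null(subjects)) seq_along(G$subjects) else {
    if (is.character(subjects)) match(subjects, G$subjects) else subjects
  }
  j <- if (is.null(snps)) seq_len(ncol(G$calls)) else {
    if (is.character(snps)) match(snps, G$snps$id) else snps
  }
  if (anyNA(i) || anyNA(j)) stop("unknown subject or SNP id", call. = FALSE)
  genotype_matrix(G$calls[i, j, drop = FALSE], G$subjects[i],
                  G$snps[j, , drop = FALSE])
}

#' Phenotype and clinical covariate table
#'
#' @param df Data frame with columns `subject_id`, `status` (0/1),
#'   `age`, `gender` (0/1), `bmi`. Subjects with any missing covariate
#'   are rejected (mirrors the study exclusion of subjects without
#'   clinical risk factors).
#' @return The validated data frame with class `phenotype_table`.
#' @export
phenotype_table <- function(df) {
  need <- c("subject_id", "status", "age", "gender", "bmi")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("phenotype table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(df[need])) {
    stop("phenotype table contains missing values; subjects without ",
         "clinical covariates must be excluded upstream", call. = FALSE)
  }
  if (!all(df$status %in% 0:1)) stop("status must be 0/1", call. = FALSE)
  if (!all(df$gender %in% 0:1)) stop("gender must be coded 0/1", call. = FALSE)
  class(df) <- c("phenotype_table", "data.frame")
  df
}

check_aligned <- function(G, P) {
  if (!identical(G$subjects, P$subject_id)) {
    stop("genotype and phenotype subjects are not aligned", call. = FALSE)
  }
  invisible(TRUE)
}

#' Risk model container
#'
#' A fitted (or oracle) logistic risk model: intercept plus named
#' coefficients on the original feature scale, with the penalty metadata
#' used at fit time. Interaction features are named `"a:b"`.
#'
#' @param features Character vector of feature names.
#' @param intercept Numeric scalar.
#' @param coefficients Numeric vector aligned with `features`.
#' @param alpha Elastic-net mixing parameter in `[0,1]` (`NA` for an
#'   unpenalized fit).
#' @param lambda Penalty strength used.
#' @param standardization Optional list with per-feature `center`/`scale`
#'   applied internally at fit time.
#' @param provenance Optional character vector classifying each feature
#'   as `"genetic"`, `"clinical"` or `"interaction"`.
#' @return Object of class `risk_model`.
#' @export
risk_model <- function(features, intercept, coefficients, alpha, lambda,
                       standardization = NULL, provenance = NULL) {
  if (length(features) != length(coefficients)) {
    stop("coefficients are not aligned with features", call. = FALSE)
  }
  if (!is.na(alpha) && (alpha < 0 || alpha > 1)) {
    stop("alpha must be in [0,1]", call. = FALSE)
  }
  structure(list(features = as.character(features),
                 intercept = unname(as.numeric(intercept)),
                 coefficients = stats::setNames(as.numeric(coefficients),
                                                features),
                 alpha = alpha, lambda = lambda,
                 standardization = standardization,
                 provenance = provenance),
            class = "risk_model")
}

#' @export
print.risk_model <- function(x, ...) {
  nz <- sum(x$coefficients != 0)
  cat(sprintf(
    "risk_model: %d features (%d nonzero), alpha = %s, lambda = %.4g\n",
    length(x$features), nz,
    ifelse(is.na(x$alpha), "unpenalized", format(x$alpha)), x$lambda))
  invisible(x)
}

#' Serialize / restore a risk model as JSON
#'
#' @param model A `risk_model`.
#' @param path File path.
#' @return `read_risk_model` returns the restored `risk_model`.
#' @export
write_risk_model <- function(model, path) {
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_risk_model
#' @export
read_risk_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  risk_model(x$features, x$intercept, x$coefficients,
             alpha = if (is.null(x$alpha)) NA_real_ else as.numeric(x$alpha),
             lambda = x$lambda,
             standardization = x$standardization,
             provenance = x$provenance)
}
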