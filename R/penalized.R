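#' Assemble the model feature matrix
#'
#' Deterministic column order: the requested SNPs in the given (rank)
#' order, then `age`, `gender`, `bmi`, then any interaction products.
#' An interaction column named `"a:b"` is the elementwise product of the
#' raw (untransformed) member columns. Missing genotype calls are
#' mean-imputed per SNP, which preserves the allele frequency.
#'
#' @param G A [genotype_matrix()].
#' @param P Aligned [phenotype_table()].
#' @param snps Ordered character vector of SNP ids (may be empty for a
#'   clinical-only matrix).
#' @param interactions List of length-2 character vectors naming feature
#'   pairs already present in the matrix.
#' @return Numeric matrix with rownames = subject ids and a
#'   `"provenance"` attribute (`"genetic"`, `"clinical"`,
#'   `"interaction"` per column).
#' @export
build_features <- function(G, P, snps = character(0),
                           interactions = list()) {
  check_aligned(G, P)
  snps <- as.character(snps)
  unknown <- setdiff(snps, G$snps$id)
  if (length(unknown)) {
    stop("unknown SNP id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  gen <- if (length(snps)) {
    impute_mean(G$calls[, snps, drop = FALSE])
  } else matrix(numeric(0), nrow = length(G$subjects), ncol = 0)
  X <- cbind(gen, age = P$age, gender = as.numeric(P$gender), bmi = P$bmi)
  prov <- c(rep("genetic", length(snps)), rep("clinical", 3L))
  for (pr in interactions) {
    pr <- as.character(pr)
    if (!all(pr %in% colnames(X))) {
      stop("interaction members not in feature set: ",
           paste(pr, collapse = ":"), call. = FALSE)
    }
    X <- cbind(X, X[, pr[1]] * X[, pr[2]])
    colnames(X)[ncol(X)] <- paste(pr, collapse = ":")
    prov <- c(prov, "interaction")
  }
  rownames(X) <- G$subjects
  attr(X, "provenance") <- stats::setNames(prov, colnames(X))
  X
}

#' Fit a penalized logistic risk model
#'
#' Minimizes `-loglik/n + lambda * [(1-alpha)/2 ||beta||_2^2 +
#' alpha ||beta||_1]` over internally standardized features (intercept
#' unpenalized) via glmnet; `alpha = 0` is ridge regression, `alpha = 1`
#' the lasso, intermediate values the elastic net. The penalty strength
#' is chosen by seeded k-fold cross-validation, by default minimizing
#' binomial deviance (`criterion = "auc"` maximizes cross-validated AUC
#' instead). Coefficients are returned on the original feature scale.
#'
#' @param X Feature matrix from [build_features()].
#' @param y 0/1 status vector.
#' @param alpha Elastic-net mixing parameter in `[0,1]`.
#' @param lambda_grid Optional decreasing lambda sequence; a single
#'   value skips cross-validation and fits at that penalty.
#' @param cv_folds Folds for the lambda search (default 10).
#' @param seed Seed for the fold assignment.
#' @param criterion `"deviance"` (default) or `"auc"`.
#' @param standardize Standardize features internally (default TRUE).
#' @param nlambda Length of the automatic lambda path.
#' @return A [risk_model()].
#' @export
fit_penalized_logistic <- function(X, y, alpha, lambda_grid = NULL,
                                   cv_folds = 10L, seed = 1L,
                                   criterion = c("deviance", "auc"),
                                   standardize = TRUE, nlambda = 100L) {
  criterion <- match.arg(criterion)
  if (length(unique(y)) < 2L) {
    stop("both classes must be present", call. = FALSE)
  }
  if (!is.null(lambda_grid) && !length(lambda_grid)) {
    stop("empty lambda grid", call. = FALSE)
  }
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0,1]", call. = FALSE)

  if (!is.null(lambda_grid) && length(lambda_grid) == 1L) {
    fit <- glmnet::glmnet(X, y, family = "binomial", alpha = alpha,
                          lambda = lambda_grid, standardize = standardize,
                          thresh = 1e-10)
    lam <- lambda_grid
  } else {
    set.seed(seed)
    foldid <- sample(rep_len(seq_len(cv_folds), length(y)))
    cv <- glmnet::cv.glmnet(X, y, family = "binomial", alpha = alpha,
                            lambda = lambda_grid, foldid = foldid,
                            nlambda = nlambda,
                            type.measure = if (criterion == "auc") "auc"
                                           else "deviance",
                            standardize = standardize)
    fit <- cv$glmnet.fit
    lam <- cv$lambda.min
  }
  co <- as.numeric(stats::coef(fit, s = lam))
  risk_model(features = colnames(X), intercept = co[1],
             coefficients = co[-1], alpha = alpha, lambda = lam,
             standardization = list(
               standardize = standardize,
               center = colMeans(X),
               scale = apply(X, 2L, stats::sd)),
             provenance = attr(X, "provenance"))
}

#' Score subjects with a fitted risk model
#'
#' `eta = intercept + X beta` on the model's features;
#' `probability = plogis(eta)`. Ranking subjects by the linear predictor
#' or the probability is equivalent.
#'
#' @param model A [risk_model()].
#' @param X Feature matrix whose columns cover the model's features.
#' @return Data frame `subject_id`, `linear_predictor`, `probability`.
#' @export
predict_risk <- function(model, X) {
  miss <- setdiff(model$features, colnames(X))
  if (length(miss)) {
    stop("feature columns missing from input: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  eta <- model$intercept +
    drop(X[, model$features, drop = FALSE] %*% model$coefficients)
  data.frame(subject_id = if (is.null(rownames(X)))
               as.character(seq_len(nrow(X))) else rownames(X),
             linear_predictor = eta,
             probability = stats::plogis(eta),
             stringsAsFactors = FALSE)
}

#' Features retained by a fitted model
#'
#' Features with exactly nonzero coefficients. Under the lasso and the
#' elastic net, coordinate-wise soft-thresholding produces exact zeros,
#' so no tolerance is applied; ridge fits return every feature.
#'
#' @param model A [risk_model()].
#' @return Character vector of feature names.
#' @export
selected_features <- function(model) {
  model$features[model$coefficients != 0]
}
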