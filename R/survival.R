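#' Score a prospective cohort with a fitted risk model
#'
#' Applies the model's linear predictor to the cohort's genotype and
#' covariate columns; no refitting on the cohort takes place. The
#' cohort table must carry one column per model feature (interaction
#' columns are derived from their members when absent).
#'
#' @param model A [risk_model()].
#' @param cohort A `survival_cohort` data frame with `subject_id`,
#'   `time`, `event` and feature columns.
#' @return The cohort with its `score` column (re)filled.
#' @export
score_cohort <- function(model, cohort) {
  base_feats <- setdiff(model$features,
                        grep(":", model$features, value = TRUE, fixed = TRUE))
  miss <- setdiff(base_feats, names(cohort))
  if (length(miss)) {
    stop("cohort lacks model feature column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  X <- as.matrix(cohort[, base_feats, drop = FALSE])
  for (ia in grep(":", model$features, value = TRUE, fixed = TRUE)) {
    mem <- strsplit(ia, ":", fixed = TRUE)[[1]]
    X <- cbind(X, cohort[[mem[1]]] * cohort[[mem[2]]])
    colnames(X)[ncol(X)] <- ia
  }
  rownames(X) <- cohort$subject_id
  cohort$score <- predict_risk(model, X)$linear_predictor
  cohort
}

#' Assign equal-sized tertile risk categories
#'
#' Subjects are sorted by risk score (ties broken by subject id) and cut
#' into three contiguous groups — low, intermediate, high — whose sizes
#' differ by at most one; a 2,116-subject cohort splits 706/705/705.
#' Rank-based boundaries (rather than score quantiles) guarantee the
#' equal sizes even with heavily tied scores.
#'
#' @param scores Numeric risk scores.
#' @param ids Optional subject ids used for deterministic tie-breaking
#'   (defaults to input order).
#' @return Factor with ordered levels `low`, `intermediate`, `high`,
#'   aligned with the input.
#' @export
tertile_categorize <- function(scores, ids = NULL) {
  n <- length(scores)
  if (n < 3L) stop("need at least three subjects", call. = FALSE)
  if (is.null(ids)) ids <- sprintf("%09d", seq_len(n))
  ord <- order(scores, ids)
  base <- n %/% 3L; rem <- n %% 3L
  sizes <- base + (seq_len(3L) <= rem)   # extras go to the lowest groups
  lab <- rep(c("low", "intermediate", "high"), times = sizes)
  out <- character(n)
  out[ord] <- lab
  factor(out, levels = c("low", "intermediate", "high"), ordered = TRUE)
}

#' Kaplan-Meier survival curves per risk category
#'
#' Product-limit estimates via [survival::survfit()], returned as a
#' plot-ready step-function table. Censored subjects leave the risk set
#' without a survival drop.
#'
#' @param times Follow-up times (>= 0).
#' @param events 0/1 event indicators.
#' @param group Factor of risk categories.
#' @return Data frame `group`, `time`, `at_risk`, `events`, `survival`.
#' @export
kaplan_meier <- function(times, events, group) {
  if (any(times < 0)) stop("negative follow-up time", call. = FALSE)
  group <- as.factor(group)
  fit <- survival::survfit(survival::Surv(times, events) ~ group)
  strata <- if (is.null(fit$strata)) {
    rep(levels(group)[1], length(fit$time))
  } else {
    rep(sub("^group=", "", names(fit$strata)), fit$strata)
  }
  data.frame(group = strata, time = fit$time, at_risk = fit$n.risk,
             events = fit$n.event, survival = fit$surv,
             stringsAsFactors = FALSE)
}

#' Log-rank test for trend across ordered risk categories
#'
#' At every distinct event time, the observed and expected events per
#' group are accumulated under the hypergeometric model; with trend
#' scores `c_g` (default 1, 2, 3), `U = sum_g c_g (O_g - E_g)` and the
#' statistic `U^2 / Var(U)` is referred to chi-squared with 1 df. With
#' two groups this reduces to the standard log-rank test.
#'
#' @param times,events As in [kaplan_meier()].
#' @param group Ordered factor (or anything coercible) of categories.
#' @param trend_scores One score per group level (default equally
#'   spaced).
#' @return List `statistic`, `p`, `observed`, `expected` (per group),
#'   `scores`.
#' @export
logrank_trend <- function(times, events, group, trend_scores = NULL) {
  group <- as.factor(group)
  lev <- levels(group)
  if (length(lev) < 2L) stop("need at least two groups", call. = FALSE)
  if (sum(events) == 0) stop("no events observed", call. = FALSE)
  if (is.null(trend_scores)) trend_scores <- seq_along(lev)
  if (length(trend_scores) != length(lev)) {
    stop("one trend score per group required", call. = FALSE)
  }
  g <- as.integer(group)
  ev_times <- sort(unique(times[events == 1]))
  nlev <- length(lev)
  O <- E <- numeric(nlev)
  varU <- 0
  for (t in ev_times) {
    at_risk <- times >= t
    n_j <- sum(at_risk)
    if (n_j < 2L) next
    d_j <- sum(events == 1 & times == t)
    n_gj <- tabulate(g[at_risk], nbins = nlev)
    d_gj <- tabulate(g[events == 1 & times == t], nbins = nlev)
    p_g <- n_gj / n_j
    O <- O + d_gj
    E <- E + d_j * p_g
    # hypergeometric variance of the score sum at this time
    varU <- varU + d_j * (n_j - d_j) / (n_j - 1) *
      (sum(trend_scores^2 * p_g) - sum(trend_scores * p_g)^2)
  }
  U <- sum(trend_scores * (O - E))
  if (varU <= 0) stop("degenerate risk sets: trend variance is zero",
                      call. = FALSE)
  stat <- U^2 / varU
  list(statistic = stat,
       p = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       observed = stats::setNames(O, lev),
       expected = stats::setNames(E, lev),
       scores = trend_scores)
}

#' Tertile/KM/trend validation of clinical-only vs combined models
#'
#' Runs the full prospective-validation pipeline — score, tertile
#' categories, Kaplan-Meier curves, log-rank trend — once per model and
#' reports the two side by side.
#'
#' @param clinical_model,combined_model Fitted [risk_model()]s.
#' @param cohort A `survival_cohort` carrying every feature of both
#'   models.
#' @return List with one element per model (`clinical`, `combined`),
#'   each `list(categories, km, trend)`, plus a `summary` data frame of
#'   the two trend tests.
#' @export
compare_clinical_vs_combined <- function(clinical_model, combined_model,
                                         cohort) {
  run <- function(model) {
    sc <- score_cohort(model, cohort)
    cat3 <- tertile_categorize(sc$score, sc$subject_id)
    list(categories = cat3,
         km = kaplan_meier(sc$time, sc$event, cat3),
         trend = logrank_trend(sc$time, sc$event, cat3))
  }
  cl <- run(clinical_model)
  cb <- run(combined_model)
  list(clinical = cl, combined = cb,
       summary = data.frame(
         model = c("clinical", "combined"),
         trend_statistic = c(cl$trend$statistic, cb$trend$statistic),
         trend_p = c(cl$trend$p, cb$trend$p)))
}
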