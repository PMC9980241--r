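#' Clinical-utility metrics for a risk score
#'
#' Given baseline and score-augmented risk models for a binary outcome,
#' these functions quantify reclassification (category-free NRI),
#' discrimination gain (incremental AUC), and effect size (odds ratio per
#' standard deviation and top-decile odds ratio), plus a phenome-style
#' association scan across many binary phenotypes.
#'
#' @name clinical_eval
NULL

#' Pair of baseline and augmented risk models
#'
#' @param baseline predicted probabilities of the baseline model
#' @param augmented predicted probabilities of the augmented (score-added)
#'   model, same samples
#' @param outcome 0/1 outcome labels
#' @return a `risk_model_pair`
#' @export
risk_model_pair <- function(baseline, augmented, outcome) {
  stopifnot(length(baseline) == length(augmented),
            length(baseline) == length(outcome),
            all(baseline >= 0 & baseline <= 1),
            all(augmented >= 0 & augmented <= 1),
            all(outcome %in% c(0, 1)))
  structure(list(baseline = baseline, augmented = augmented,
                 outcome = as.integer(outcome)), class = "risk_model_pair")
}

.check_two_classes <- function(outcome) {
  if (length(unique(outcome)) < 2) stop("outcome has a single class")
}

.nri_point <- function(base, aug, y) {
  up <- aug > base          # ties count as neither up nor down
  down <- aug < base
  case <- y == 1
  nri_cases <- mean(up[case]) - mean(down[case])
  nri_controls <- mean(down[!case]) - mean(up[!case])
  c(cases = nri_cases, controls = nri_controls,
    total = nri_cases + nri_controls)
}

#' Category-free net reclassification improvement
#'
#' `NRI = P(up|case) - P(down|case) + P(down|control) - P(up|control)`,
#' where "up"/"down" mean a strict increase/decrease of predicted risk
#' from the baseline to the augmented model (ties count as neither). The
#' confidence interval is a percentile bootstrap over samples.
#'
#' @param pair a [risk_model_pair()]
#' @param n_bootstrap bootstrap replicates (default 500)
#' @param seed bootstrap seed
#' @return an `nri_result`: `nri_total`, `nri_cases`, `nri_controls`,
#'   `ci95`, `n_bootstrap`, `n_ties`
#' @export
category_free_nri <- function(pair, n_bootstrap = 500, seed = 1) {
  stopifnot(inherits(pair, "risk_model_pair"), n_bootstrap >= 1)
  .check_two_classes(pair$outcome)
  pt <- .nri_point(pair$baseline, pair$augmented, pair$outcome)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n <- length(pair$outcome)
  boot <- replicate(n_bootstrap, {
    i <- sample.int(n, n, replace = TRUE)
    if (length(unique(pair$outcome[i])) < 2) NA_real_
    else .nri_point(pair$baseline[i], pair$augmented[i],
                    pair$outcome[i])["total"]
  })
  ci <- unname(stats::quantile(boot, c(0.025, 0.975), na.rm = TRUE))
  structure(list(nri_total = unname(pt["total"]),
                 nri_cases = unname(pt["cases"]),
                 nri_controls = unname(pt["controls"]),
                 ci95 = ci, n_bootstrap = n_bootstrap,
                 n_ties = sum(pair$augmented == pair$baseline)),
            class = "nri_result")
}

#' @export
print.nri_result <- function(x, ...) {
  cat(sprintf("<nri_result> NRI = %.3f (cases %.3f + controls %.3f), 95%% CI [%.3f, %.3f]\n",
              x$nri_total, x$nri_cases, x$nri_controls, x$ci95[1], x$ci95[2]))
  invisible(x)
}

#' Area under the ROC curve (rank formulation)
#'
#' Concordance probability: the fraction of case-control pairs in which
#' the case receives the higher prediction, ties counted one half.
#'
#' @param pred predictions (any monotone risk scale)
#' @param outcome 0/1 labels
#' @return AUC in `[0, 1]`
#' @export
rank_auc <- function(pred, outcome) {
  .check_two_classes(outcome)
  n1 <- sum(outcome == 1)
  n0 <- sum(outcome == 0)
  r <- rank(pred)                       # midranks handle ties as 1/2
  (sum(r[outcome == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Incremental AUC of the augmented model
#'
#' `AUC(augmented) - AUC(baseline)` with a percentile bootstrap CI over
#' samples.
#'
#' @inheritParams category_free_nri
#' @return list with `delta_auc`, `auc_baseline`, `auc_augmented`, `ci95`,
#'   `n_bootstrap`
#' @export
incremental_auc <- function(pair, n_bootstrap = 500, seed = 1) {
  stopifnot(inherits(pair, "risk_model_pair"), n_bootstrap >= 1)
  .check_two_classes(pair$outcome)
  a0 <- rank_auc(pair$baseline, pair$outcome)
  a1 <- rank_auc(pair$augmented, pair$outcome)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n <- length(pair$outcome)
  boot <- replicate(n_bootstrap, {
    i <- sample.int(n, n, replace = TRUE)
    if (length(unique(pair$outcome[i])) < 2) NA_real_
    else rank_auc(pair$augmented[i], pair$outcome[i]) -
      rank_auc(pair$baseline[i], pair$outcome[i])
  })
  list(delta_auc = a1 - a0, auc_baseline = a0, auc_augmented = a1,
       ci95 = unname(stats::quantile(boot, c(0.025, 0.975), na.rm = TRUE)),
       n_bootstrap = n_bootstrap)
}

.logistic_or <- function(x, outcome, covariates, label) {
  n <- length(outcome)
  X <- .model_matrix(covariates, n)
  fit <- if (is.null(X))
    stats::glm(outcome ~ x, family = stats::binomial())
  else
    stats::glm(outcome ~ x + X, family = stats::binomial())
  co <- summary(fit)$coefficients
  b <- co["x", "Estimate"]; se <- co["x", "Std. Error"]
  if (!fit$converged || abs(b) > 15 || se > 100)
    stop("(quasi-)separation detected in the ", label, " logistic model")
  list(or = exp(b), ci95 = exp(b + c(-1, 1) * stats::qnorm(0.975) * se),
       log_or = b, se = se, p_value = co["x", "Pr(>|z|)"])
}

#' Odds ratio per standard deviation of the score
#'
#' Standardizes the score over the evaluation sample and reports
#' `exp(coefficient)` from a covariate-adjusted logistic fit, with a Wald
#' 95% CI.
#'
#' @param score numeric score vector
#' @param outcome 0/1 outcome
#' @param covariates optional covariate matrix
#' @return list with `or`, `ci95`, `log_or`, `se`, `p_value`
#' @export
or_per_sd <- function(score, outcome, covariates = NULL) {
  .check_two_classes(outcome)
  z <- as.numeric(scale(score))
  .logistic_or(z, outcome, covariates, "per-SD")
}

#' Top-decile versus remainder odds ratio
#'
#' Compares individuals whose score exceeds the evaluation sample's 90th
#' percentile against the remaining population (ties at or below the
#' threshold stay in the remainder) with a covariate-adjusted logistic
#' fit.
#'
#' @inheritParams or_per_sd
#' @return list with `or`, `ci95`, `log_or`, `se`, `p_value`, `n_top`
#' @export
top_decile_or <- function(score, outcome, covariates = NULL) {
  stopifnot(length(score) >= 20)
  .check_two_classes(outcome)
  thr <- stats::quantile(score, 0.9, names = FALSE)
  top <- as.numeric(score > thr)
  if (sum(top) == 0) stop("top decile is empty (ties at the threshold)")
  res <- .logistic_or(top, outcome, covariates, "top-decile")
  res$n_top <- sum(top)
  res
}

#' Phenome-style association scan of a score
#'
#' One covariate-adjusted logistic regression of each binary phenotype
#' column on the score; significance at the Bonferroni level
#' `alpha / n_tested`. Columns with a single class are skipped with a
#' warning.
#'
#' @param score numeric score vector
#' @param phenotypes samples x phenotypes 0/1 matrix or data frame
#' @param covariates optional covariate matrix
#' @param alpha family-wise significance level (default 0.05)
#' @return an `assoc_scan_result`: data frame `results` (phenotype,
#'   estimate, se, p_value, significant), `bonferroni` threshold,
#'   `skipped` column names
#' @export
assoc_scan <- function(score, phenotypes, covariates = NULL, alpha = 0.05) {
  P <- as.matrix(phenotypes)
  stopifnot(ncol(P) >= 1, nrow(P) == length(score))
  if (is.null(colnames(P))) colnames(P) <- paste0("pheno", seq_len(ncol(P)))
  testable <- apply(P, 2, function(y) length(unique(y)) == 2)
  if (any(!testable))
    warning("skipping single-class phenotype(s): ",
            paste(colnames(P)[!testable], collapse = ", "), call. = FALSE)
  cols <- colnames(P)[testable]
  n_tested <- length(cols)
  if (n_tested == 0) stop("no testable phenotype column")
  thr <- alpha / n_tested
  X <- .model_matrix(covariates, length(score))
  rows <- lapply(cols, function(nm) {
    y <- P[, nm]
    fit <- if (is.null(X))
      stats::glm(y ~ score, family = stats::binomial())
    else stats::glm(y ~ score + X, family = stats::binomial())
    co <- summary(fit)$coefficients
    data.frame(phenotype = nm, estimate = co["score", "Estimate"],
               se = co["score", "Std. Error"],
               p_value = co["score", "Pr(>|z|)"],
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$significant <- res$p_value < thr
  structure(list(results = res, bonferroni = thr, n_tested = n_tested,
                 skipped = colnames(P)[!testable]),
            class = "assoc_scan_result")
}

#' @export
print.assoc_scan_result <- function(x, ...) {
  cat("<assoc_scan_result> ", x$n_tested, " phenotypes tested, ",
      sum(x$results$significant), " significant at Bonferroni ",
      format(x$bonferroni, digits = 3), "\n", sep = "")
  invisible(x)
}

#' Fit baseline and augmented logistic risk models
#'
#' Convenience wrapper: fits `outcome ~ covariates (+ risk factors)` and
#' the same model plus the score, returning fitted probabilities as a
#' [risk_model_pair()] ready for [category_free_nri()] and
#' [incremental_auc()].
#'
#' @param score numeric score vector
#' @param outcome 0/1 outcome
#' @param covariates covariate matrix for the baseline model (age, sex,
#'   PCs, clinical risk factors)
#' @return a `risk_model_pair`
#' @export
fit_risk_models <- function(score, outcome, covariates) {
  .check_two_classes(outcome)
  X <- .model_matrix(covariates, length(outcome))
  base <- stats::glm(outcome ~ X, family = stats::binomial())
  aug <- stats::glm(outcome ~ score + X, family = stats::binomial())
  risk_model_pair(stats::fitted(base), stats::fitted(aug), outcome)
}
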