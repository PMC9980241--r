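#' Accuracy, power and variance of polygenic-score prediction
#'
#' A candidate score is judged by the variance it explains over and above
#' covariates (partial R2; converted to the liability scale for binary
#' traits), by the analytic power of its association test, and by the
#' theoretical standard error of R2. Scores with power above a threshold
#' (default 0.95) and a significant association are retained for the
#' mixing step.
#'
#' @name prs_stats
NULL

#' Non-centrality parameter of the score association test
#'
#' `lambda = n * r2 / (1 - r2)`: the non-centrality of the 1-df chi-square
#' statistic for the test of association between score and trait when the
#' score explains a fraction `r2` of trait variance in a sample of size `n`.
#'
#' @param n evaluation sample size (>= 1)
#' @param r2 prediction accuracy, in `[0, 1)`
#' @return non-centrality parameter `lambda >= 0`
#' @export
prs_ncp <- function(n, r2) {
  stopifnot(n >= 1)
  if (any(r2 < 0) || any(r2 >= 1)) stop("r2 must lie in [0, 1)")
  n * r2 / (1 - r2)
}

#' Analytic power of the two-tailed score association test
#'
#' Normal-approximation power of the two-sided association test:
#' `1 - Phi(z_{1-alpha/2} - sqrt(lambda)) + Phi(z_{alpha/2} - sqrt(lambda))`
#' with `lambda` from [prs_ncp()]. This agrees with the upper-tail mass of
#' a non-central chi-square(1, lambda) beyond the central critical value to
#' about 1e-3 over the practical grid.
#'
#' @inheritParams prs_ncp
#' @param alpha two-sided significance level in `(0, 1)`
#' @return power in `[alpha, 1]`
#' @export
prs_power <- function(n, r2, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  s <- sqrt(prs_ncp(n, r2))
  1 - stats::pnorm(stats::qnorm(1 - alpha / 2) - s) +
    stats::pnorm(stats::qnorm(alpha / 2) - s)
}

#' Theoretical standard error of an estimated R2
#'
#' `var(R2) = 4 r2 (1 - r2)^2 (n - 2)^2 / ((n^2 - 1)(n + 3))`, the classical
#' large-sample variance of the squared multiple correlation; the standard
#' error is its square root.
#'
#' @param r2 accuracy in `[0, 1)`
#' @param n sample size (> 3)
#' @return standard error of R2
#' @export
r2_se <- function(r2, n) {
  if (any(n <= 3)) stop("n must exceed 3")
  if (any(r2 < 0) || any(r2 >= 1)) stop("r2 must lie in [0, 1)")
  sqrt(4 * r2 * (1 - r2)^2 * (n - 2)^2 / ((n^2 - 1) * (n + 3)))
}

.model_matrix <- function(covariates, n) {
  if (is.null(covariates)) return(NULL)
  x <- as.matrix(covariates)
  stopifnot(nrow(x) == n)
  x
}

.accuracy_estimate <- function(r2, scale, n, p_value, alpha,
                               prevalence = NULL) {
  r2 <- max(0, min(r2, 1 - 1e-12))
  structure(list(r2 = r2, scale = scale, se_r2 = r2_se(r2, n),
                 ncp = prs_ncp(n, r2), power = prs_power(n, r2, alpha),
                 p_value = p_value, n = n, prevalence = prevalence),
            class = "accuracy_estimate")
}

#' @export
print.accuracy_estimate <- function(x, ...) {
  cat(sprintf("<accuracy_estimate> %s R2 = %.4g (se %.3g), power = %.3f, p = %.3g, n = %d\n",
              x$scale, x$r2, x$se_r2, x$power, x$p_value, x$n))
  invisible(x)
}

#' Partial R2 of a score for a continuous trait
#'
#' The difference in R2 between the full least-squares model
#' (trait ~ score + covariates) and the null model (trait ~ covariates):
#' the variance explained by the score over and above the covariates. The
#' p-value is from the nested-model F comparison.
#'
#' @param phenotype continuous trait vector
#' @param score score vector
#' @param covariates optional numeric matrix/data frame of covariates
#'   (e.g. age, sex, 10 PCs)
#' @param alpha significance level used for the power computation
#' @return an `accuracy_estimate` with `scale = "observed-partial"`
#' @export
partial_r2 <- function(phenotype, score, covariates = NULL, alpha = 0.05) {
  n <- length(phenotype)
  stopifnot(length(score) == n)
  if (stats::sd(score) == 0) stop("score is constant")
  X <- .model_matrix(covariates, n)
  if (n <= (if (is.null(X)) 0 else ncol(X)) + 2)
    stop("too few samples for the covariate set")

  if (is.null(X)) {
    full <- stats::lm(phenotype ~ score)
    null <- stats::lm(phenotype ~ 1)
  } else {
    res <- stats::lm.fit(cbind(1, X), score)$residuals
    if (stats::sd(res) < 1e-8 * stats::sd(score))
      stop("score is collinear with the covariates")
    full <- stats::lm(phenotype ~ score + X)
    null <- stats::lm(phenotype ~ X)
  }
  r2 <- summary(full)$r.squared - summary(null)$r.squared
  cmp <- stats::anova(null, full)
  p <- cmp[["Pr(>F)"]][2]
  .accuracy_estimate(r2, "observed-partial", n, p, alpha)
}

#' Liability-scale transformation factor
#'
#' Multiplier converting observed-scale R2 of a 0/1 trait to the latent
#' liability scale: `K^2 (1-K)^2 / (z^2 P (1-P))` with `z` the standard
#' normal density at the K-quantile, `K` the population prevalence and `P`
#' the sample prevalence. With `P = K` (prevalence approximated by the
#' sample, the default) this reduces to `K (1-K) / z^2`, which equals
#' `pi / 2` at `K = 0.5`.
#'
#' @param K population disease prevalence in `(0, 1)`
#' @param P sample prevalence in `(0, 1)`; defaults to `K`
#' @return positive scalar factor
#' @export
liability_factor <- function(K, P = K) {
  stopifnot(K > 0, K < 1, P > 0, P < 1)
  z <- stats::dnorm(stats::qnorm(K))
  K^2 * (1 - K)^2 / (z^2 * P * (1 - P))
}

#' Liability-scale R2 of a score for a binary trait
#'
#' Computes the observed-scale partial R2 by least squares on the 0/1
#' outcome (linear probability model) and multiplies it by
#' [liability_factor()]. By default the population prevalence K is
#' approximated by the sample prevalence. The p-value is the Wald test on
#' the score coefficient in a covariate-adjusted logistic model.
#'
#' @param phenotype 0/1 outcome vector (both classes present)
#' @param score score vector
#' @param covariates optional covariate matrix
#' @param prevalence optional population prevalence K; when `NULL` the
#'   sample prevalence is used
#' @param alpha significance level for the power computation
#' @return an `accuracy_estimate` with `scale = "liability"`
#' @export
liability_r2 <- function(phenotype, score, covariates = NULL,
                         prevalence = NULL, alpha = 0.05) {
  phenotype <- as.numeric(phenotype)
  if (length(unique(phenotype)) < 2) stop("phenotype has a single class")
  stopifnot(all(phenotype %in% c(0, 1)))
  n <- length(phenotype)
  P <- mean(phenotype)
  K <- if (is.null(prevalence)) P else prevalence

  obs <- partial_r2(phenotype, score, covariates, alpha)
  X <- .model_matrix(covariates, n)
  fit <- if (is.null(X))
    stats::glm(phenotype ~ score, family = stats::binomial())
  else
    stats::glm(phenotype ~ score + X, family = stats::binomial())
  p <- summary(fit)$coefficients["score", "Pr(>|z|)"]

  r2_liab <- obs$r2 * liability_factor(K, P)
  .accuracy_estimate(r2_liab, "liability", n, p, alpha, prevalence = K)
}

#' Retention rule for high-power scores
#'
#' @param power_threshold retain scores with power strictly above this
#'   (default 0.95)
#' @param p_threshold retain scores with association p-value at or below
#'   this (default 0.05; a Bonferroni level such as 0.05/2600 may be
#'   supplied instead)
#' @return a `selection_rule` object
#' @export
selection_rule <- function(power_threshold = 0.95, p_threshold = 0.05) {
  stopifnot(power_threshold > 0, power_threshold < 1,
            p_threshold > 0, p_threshold < 1)
  structure(list(power_threshold = power_threshold,
                 p_threshold = p_threshold), class = "selection_rule")
}

#' Select high-power scores
#'
#' Retains the scores with `power > power_threshold` and
#' `p_value <= p_threshold`. Deterministic and order-preserving.
#'
#' @param stats a data frame with columns `score_id`, `power`, `p_value`
#'   (e.g. from [evaluate_panel()])
#' @param rule a [selection_rule()]
#' @return character vector of retained score ids (possibly empty)
#' @export
select_high_power <- function(stats, rule = selection_rule()) {
  if (nrow(stats) == 0) return(character())
  keep <- stats$power > rule$power_threshold &
    stats$p_value <= rule$p_threshold
  stats$score_id[keep]
}

#' Evaluate every score of a panel against a trait
#'
#' Applies [partial_r2()] (continuous) or [liability_r2()] (binary) to each
#' column of a score panel and tabulates accuracy, power and p-value.
#'
#' @param panel a `score_panel`
#' @param phenotype trait vector aligned with the panel's samples
#' @param covariates optional covariate matrix
#' @param family `"continuous"` or `"binary"`
#' @param alpha significance level for power
#' @return data frame: score_id, trait_label, scale, r2, se_r2, power,
#'   p_value, n
#' @export
evaluate_panel <- function(panel, phenotype, covariates = NULL,
                           family = c("continuous", "binary"),
                           alpha = 0.05) {
  family <- match.arg(family)
  est <- lapply(panel$score_ids, function(id) {
    s <- panel$values[, id]
    if (family == "continuous") partial_r2(phenotype, s, covariates, alpha)
    else liability_r2(phenotype, s, covariates, alpha = alpha)
  })
  data.frame(
    score_id = panel$score_ids,
    trait_label = panel$meta$trait_label,
    scale = vapply(est, `[[`, "", "scale"),
    r2 = vapply(est, `[[`, 0, "r2"),
    se_r2 = vapply(est, `[[`, 0, "se_r2"),
    power = vapply(est, `[[`, 0, "power"),
    p_value = vapply(est, `[[`, 0, "p_value"),
    n = vapply(est, `[[`, 0L, "n"),
    stringsAsFactors = FALSE
  )
}
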