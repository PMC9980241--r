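#' Train penalized linear combinations of polygenic scores
#'
#' The mixing step regresses the trait on the standardized candidate scores
#' (plus unpenalized covariates) with an elastic-net penalty, the penalty
#' strength chosen by 5-fold cross-validation. The mixing weight of score i
#' on the standardized scale, omega_i, is divided by the training-set
#' standard deviation sigma_i to give the adjusted weight
#' alpha_i = omega_i / sigma_i applicable to raw scores, and the combined
#' per-allele SNP effect of variant j is gamma_j = sum_i alpha_i * beta_ji
#' with beta_ji = 0 where variant j is absent from score i.
#'
#' @name mixer
NULL

#' Train/test split specification
#'
#' @param train_fraction fraction of samples assigned to training
#'   (default 0.8)
#' @param seed integer seed controlling the split
#' @param stratify stratify on case status for binary traits
#'   (default `TRUE`)
#' @return a `split_spec` object
#' @export
split_spec <- function(train_fraction = 0.8, seed = 42, stratify = TRUE) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  structure(list(train_fraction = train_fraction, seed = as.integer(seed),
                 stratify = isTRUE(stratify)), class = "split_spec")
}

#' Split samples into training and testing sets
#'
#' Disjoint, exhaustive partition, deterministic given the seed. For binary
#' phenotypes with `stratify = TRUE` the split is drawn within cases and
#' controls separately, preserving prevalence to within one sample per
#' stratum.
#'
#' @param sample_ids vector of sample identifiers
#' @param phenotype trait vector (used only for stratification)
#' @param spec a [split_spec()]
#' @return list with `train` and `test` id vectors
#' @export
split_samples <- function(sample_ids, phenotype = NULL, spec = split_spec()) {
  n <- length(sample_ids)
  stopifnot(n >= 10)
  is_binary <- !is.null(phenotype) && all(phenotype %in% c(0, 1))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)

  if (is_binary && spec$stratify) {
    train_idx <- integer()
    for (cls in sort(unique(phenotype))) {
      idx <- which(phenotype == cls)
      k <- round(spec$train_fraction * length(idx))
      if (k == 0 || k == length(idx))
        stop("a phenotype stratum would be empty in train or test")
      train_idx <- c(train_idx, sample(idx, k))
    }
  } else {
    k <- round(spec$train_fraction * n)
    if (k == 0 || k == n) stop("degenerate split")
    train_idx <- sample.int(n, k)
  }
  train_idx <- sort(train_idx)
  list(train = sample_ids[train_idx], test = sample_ids[-train_idx])
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

.panel_values <- function(panel) {
  if (inherits(panel, "score_panel")) panel$values else as.matrix(panel)
}

#' Fit the penalized mixture of scores
#'
#' Standardizes each score to mean 0 / variance 1 using training
#' statistics, then fits an elastic-net linear (continuous) or logistic
#' (binary) model of the trait on the standardized scores, with covariates
#' included unpenalized. The penalty strength is chosen by k-fold
#' cross-validation at minimum CV loss. The adjusted weights
#' `alpha_adj = omega / sigma` apply to raw (unstandardized) scores.
#'
#' @param panel a `score_panel` or samples x scores matrix (training rows
#'   only)
#' @param phenotype training trait vector
#' @param covariates optional training covariate matrix, never penalized
#' @param family `"continuous"` or `"binary"`
#' @param mix_alpha elastic-net mixing parameter between the L1 and L2
#'   penalties (default 0.5)
#' @param nfolds number of CV folds (default 5)
#' @param seed seed controlling fold assignment
#' @return an object of class `mix_weights` with `score_ids`, `omega`
#'   (standardized-scale coefficients), `sigma` (training SDs),
#'   `alpha_adj`, `intercept`, `covar_coef`, `family`, `lambda`,
#'   `mix_alpha` and `informative` (`FALSE` when CV selects the all-zero
#'   score model)
#' @export
fit_mixture <- function(panel, phenotype, covariates = NULL,
                        family = c("continuous", "binary"),
                        mix_alpha = 0.5, nfolds = 5, seed = 42) {
  family <- match.arg(family)
  S <- .panel_values(panel)
  k <- ncol(S)
  n <- nrow(S)
  stopifnot(k >= 1, length(phenotype) == n)
  sigma <- apply(S, 2, stats::sd)
  if (any(sigma == 0))
    stop("zero-variance score(s): ",
         paste(colnames(S)[sigma == 0], collapse = ", "))
  mu <- colMeans(S)
  Z <- scale(S, center = mu, scale = sigma)
  X <- .model_matrix(covariates, n)
  glm_family <- if (family == "binary") "binomial" else "gaussian"

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  foldid <- sample(rep(seq_len(nfolds), length.out = n))
  if (family == "binary") {
    for (f in seq_len(nfolds))
      if (length(unique(phenotype[foldid == f])) < 2)
        stop("a CV fold contains a single phenotype class")
  }

  design <- cbind(Z, X)
  if (ncol(design) < 2) {
    # one score, no covariates: the penalized path degenerates to a plain fit
    fit <- stats::glm(phenotype ~ Z,
                      family = if (family == "binary") stats::binomial()
                               else stats::gaussian())
    omega <- unname(stats::coef(fit)[2])
    intercept <- unname(stats::coef(fit)[1])
    covar_coef <- numeric(0)
    lambda <- 0
  } else {
    pf <- c(rep(1, k), rep(0, if (is.null(X)) 0 else ncol(X)))
    cv <- glmnet::cv.glmnet(design, phenotype, family = glm_family,
                            alpha = mix_alpha, foldid = foldid,
                            penalty.factor = pf, standardize = FALSE,
                            thresh = 1e-10)
    co <- as.numeric(stats::coef(cv, s = "lambda.min"))
    intercept <- co[1]
    omega <- co[1 + seq_len(k)]
    covar_coef <- co[-seq_len(1 + k)]
    lambda <- cv$lambda.min
  }

  structure(list(score_ids = colnames(S), omega = omega, sigma = sigma,
                 mean = mu, alpha_adj = omega / sigma,
                 intercept = intercept, covar_coef = covar_coef,
                 family = family, lambda = lambda, mix_alpha = mix_alpha,
                 informative = any(omega != 0)),
            class = "mix_weights")
}

#' @export
print.mix_weights <- function(x, ...) {
  cat("<mix_weights> ", length(x$score_ids), " scores (",
      sum(x$omega != 0), " non-zero), family = ", x$family, "\n", sep = "")
  print(data.frame(score_id = x$score_ids, omega = x$omega,
                   sigma = x$sigma, alpha_adj = x$alpha_adj))
  invisible(x)
}

#' Apply fitted mixing weights to raw scores
#'
#' Combined raw score per sample: `sum_i alpha_adj_i * PRS_i`. This equals
#' the standardized-scale linear predictor up to an additive constant,
#' which R2 and logistic evaluation ignore.
#'
#' @param weights a `mix_weights`
#' @param panel a `score_panel` or matrix containing at least the fitted
#'   score columns
#' @return numeric vector of combined scores
#' @export
combine_scores <- function(weights, panel) {
  V <- .panel_values(panel)
  miss <- setdiff(weights$score_ids, colnames(V))
  if (length(miss)) stop("panel lacks fitted scores: ",
                         paste(miss, collapse = ", "))
  drop(V[, weights$score_ids, drop = FALSE] %*% weights$alpha_adj)
}

#' Derive combined per-allele SNP effects
#'
#' `gamma_j = sum_i alpha_adj_i * beta_ji` over the union of variants of
#' the contributing harmonized scorings, with `beta_ji = 0` where variant j
#' is absent from score i. The model intercept is discarded (location
#' only).
#'
#' @param weights a `mix_weights`
#' @param scorings list of `harmonized_scoring` objects covering
#'   `weights$score_ids`
#' @return an object of class `adjusted_effects`: list with `variants`
#'   (chr, pos, ref, alt), `gamma` and `provenance` (score_id, alpha_adj)
#' @export
derive_snp_effects <- function(weights, scorings) {
  ids <- vapply(scorings, `[[`, "", "score_id")
  if (!all(weights$score_ids %in% ids))
    stop("scorings missing for: ",
         paste(setdiff(weights$score_ids, ids), collapse = ", "))
  recs <- lapply(weights$score_ids, function(id) {
    rec <- scorings[[match(id, ids)]]$records
    rec$key <- variant_key(rec$chr, rec$pos, rec$ref, rec$alt)
    rec
  })
  all_rec <- do.call(rbind, recs)
  ukey <- unique(all_rec$key)
  variants <- all_rec[match(ukey, all_rec$key),
                      c("chr", "pos", "ref", "alt")]
  rownames(variants) <- NULL
  gamma <- numeric(length(ukey))
  for (i in seq_along(recs)) {
    j <- match(recs[[i]]$key, ukey)
    gamma[j] <- gamma[j] + weights$alpha_adj[i] * recs[[i]]$weight
  }
  names(gamma) <- ukey
  structure(list(variants = variants,
                 gamma = gamma,
                 provenance = data.frame(score_id = weights$score_ids,
                                         alpha_adj = weights$alpha_adj,
                                         stringsAsFactors = FALSE),
                 score_id = "combined", trait_label = NA_character_),
            class = "adjusted_effects")
}

#' @export
print.adjusted_effects <- function(x, ...) {
  cat("<adjusted_effects> ", nrow(x$variants), " variants from ",
      nrow(x$provenance), " scores\n", sep = "")
  invisible(x)
}

#' Convert adjusted effects to a harmonized scoring
#'
#' Convenience for re-scoring a cohort with the combined per-allele
#' effects via [compute_prs()].
#'
#' @param effects an `adjusted_effects`
#' @return a `harmonized_scoring`
#' @export
as_harmonized_scoring <- function(effects) {
  stopifnot(inherits(effects, "adjusted_effects"))
  rec <- effects$variants
  rec$weight <- unname(effects$gamma)
  structure(list(score_id = effects$score_id,
                 trait_label = effects$trait_label,
                 records = rec, n_flipped = 0L, n_dropped = 0L),
            class = "harmonized_scoring")
}

.evaluate_one <- function(phenotype, score, covariates, family, alpha) {
  if (family == "continuous") partial_r2(phenotype, score, covariates, alpha)
  else liability_r2(phenotype, score, covariates, alpha = alpha)
}

.mix_pipeline <- function(panel, keep_ids, phenotype, covariates, family,
                          spec, rule, scorings, mix_alpha, nfolds, alpha) {
  if (length(keep_ids) == 0) stop("no candidate score matches the outcome trait")
  split <- split_samples(panel$sample_ids, phenotype, spec)
  tr <- match(split$train, panel$sample_ids)
  te <- match(split$test, panel$sample_ids)
  sub_cov <- function(idx)
    if (is.null(covariates)) NULL
    else as.matrix(covariates)[idx, , drop = FALSE]

  V <- panel$values[, keep_ids, drop = FALSE]
  train_panel <- score_panel(V[tr, , drop = FALSE],
                             meta = panel$meta[match(keep_ids,
                                                     panel$meta$score_id), ],
                             sample_ids = split$train)
  train_stats <- evaluate_panel(train_panel, phenotype[tr], sub_cov(tr),
                                family = family, alpha = alpha)
  retained <- if (is.null(rule)) keep_ids
              else select_high_power(train_stats, rule)
  if (length(retained) == 0)
    stop("no candidate score survives the power filter")

  weights <- fit_mixture(V[tr, retained, drop = FALSE], phenotype[tr],
                         sub_cov(tr), family = family,
                         mix_alpha = mix_alpha, nfolds = nfolds,
                         seed = spec$seed)

  test_accuracy <- NULL
  if (weights$informative) {
    combined_test <- combine_scores(weights, V[te, , drop = FALSE])
    test_accuracy <- .evaluate_one(phenotype[te], combined_test,
                                   sub_cov(te), family, alpha)
  } else {
    warning("cross-validation selected the all-zero score model; ",
            "the combination is non-informative", call. = FALSE)
  }

  # best single candidate: chosen on the TRAINING split, scored on TEST
  best_id <- train_stats$score_id[which.max(train_stats$r2)]
  best_single <- .evaluate_one(phenotype[te], V[te, best_id],
                               sub_cov(te), family, alpha)

  effects <- if (!is.null(scorings) && weights$informative)
    derive_snp_effects(weights, scorings) else NULL

  structure(list(weights = weights, effects = effects,
                 test_accuracy = test_accuracy,
                 best_single = best_single, best_single_id = best_id,
                 fold_ratio = if (!is.null(test_accuracy))
                   test_accuracy$r2 / best_single$r2 else NA_real_,
                 retained = retained, train_stats = train_stats,
                 split = split, family = family),
            class = "prs_mix_result")
}

#' @export
print.prs_mix_result <- function(x, ...) {
  cat("<prs_mix_result> ", length(x$retained), " scores mixed; ",
      "test R2 = ",
      if (is.null(x$test_accuracy)) "NA (non-informative)"
      else format(x$test_accuracy$r2, digits = 4),
      "; best single ('", x$best_single_id, "') R2 = ",
      format(x$best_single$r2, digits = 4),
      "; fold-ratio = ", format(x$fold_ratio, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Trait-specific score combination
#'
#' Restricts the panel to scores whose trait label matches the outcome
#' trait (exact string, case-normalized), filters them by power on the
#' training split, fits the penalized mixture, optionally derives combined
#' per-allele effects, and evaluates the combined score and the
#' best-single baseline on the held-out test split.
#'
#' @param panel a `score_panel` with trait labels in `panel$meta`
#' @param trait_label outcome trait label to match
#' @param phenotype trait vector aligned with the panel samples
#' @param covariates optional covariate matrix
#' @param family `"continuous"` or `"binary"`
#' @param spec a [split_spec()]
#' @param rule a [selection_rule()], or `NULL` to skip the power filter
#' @param scorings optional list of `harmonized_scoring` objects used to
#'   derive per-allele effects
#' @param mix_alpha,nfolds elastic-net mixing parameter and CV folds
#' @param alpha significance level for accuracy/power estimates
#' @return a `prs_mix_result`: `weights` (a `mix_weights`), `effects`
#'   (an `adjusted_effects` or `NULL`), `test_accuracy`, `best_single`,
#'   `fold_ratio`, `retained`, `train_stats`, `split`
#' @export
prsmix <- function(panel, trait_label, phenotype, covariates = NULL,
                   family = c("continuous", "binary"),
                   spec = split_spec(), rule = selection_rule(),
                   scorings = NULL, mix_alpha = 0.5, nfolds = 5,
                   alpha = 0.05) {
  family <- match.arg(family)
  keep <- panel$score_ids[!is.na(panel$meta$trait_label) &
                            tolower(panel$meta$trait_label) ==
                            tolower(trait_label)]
  .mix_pipeline(panel, keep, phenotype, covariates, family, spec, rule,
                scorings, mix_alpha, nfolds, alpha)
}

#' Cross-trait score combination
#'
#' Identical to [prsmix()] but places no trait-label restriction on the
#' candidate set: every high-power score in the panel — including the
#' outcome trait's own — enters the penalized fit, letting correlated
#' traits contribute pleiotropic signal.
#'
#' @inheritParams prsmix
#' @return a `prs_mix_result`
#' @export
prsmix_plus <- function(panel, phenotype, covariates = NULL,
                        family = c("continuous", "binary"),
                        spec = split_spec(), rule = selection_rule(),
                        scorings = NULL, mix_alpha = 0.5, nfolds = 5,
                        alpha = 0.05) {
  family <- match.arg(family)
  .mix_pipeline(panel, panel$score_ids, phenotype, covariates, family,
                spec, rule, scorings, mix_alpha, nfolds, alpha)
}

#' Test the mean fold-ratio of accuracy across traits
#'
#' Elementwise fold-ratios `r2_combined / r2_best_single` across traits,
#' their mean with a normal-theory 95% confidence interval, and a
#' two-tailed one-sample t-test of the ratios against 1. With
#' `paired = TRUE` the t-test is instead the paired t-test on the two R2
#' vectors.
#'
#' @param r2_combined,r2_best_single positive per-trait accuracy vectors of
#'   equal length (>= 2)
#' @param paired use the paired-R2 t-test variant
#' @return an `improvement_result`: `fold_ratios`, `mean_ratio`, `ci95`,
#'   `p_value`
#' @export
improvement_test <- function(r2_combined, r2_best_single, paired = FALSE) {
  stopifnot(length(r2_combined) == length(r2_best_single),
            length(r2_combined) >= 2)
  if (any(r2_combined <= 0) || any(r2_best_single <= 0))
    stop("R2 values must be positive")
  ratios <- r2_combined / r2_best_single
  if (stats::sd(ratios) == 0 && !paired) {
    return(structure(list(fold_ratios = ratios, mean_ratio = mean(ratios),
                          ci95 = c(mean(ratios), mean(ratios)),
                          p_value = if (all(ratios == 1)) 1 else NA_real_,
                          degenerate = TRUE),
                     class = "improvement_result"))
  }
  tt <- if (paired) stats::t.test(r2_combined, r2_best_single, paired = TRUE)
        else stats::t.test(ratios, mu = 1)
  ci <- mean(ratios) + c(-1, 1) * stats::qt(0.975, length(ratios) - 1) *
    stats::sd(ratios) / sqrt(length(ratios))
  structure(list(fold_ratios = ratios, mean_ratio = mean(ratios),
                 ci95 = ci, p_value = tt$p.value, degenerate = FALSE),
            class = "improvement_result")
}

#' @export
print.improvement_result <- function(x, ...) {
  cat(sprintf("<improvement_result> mean fold-ratio %.3f (95%% CI %.3f-%.3f), p = %.3g\n",
              x$mean_ratio, x$ci95[1], x$ci95[2], x$p_value))
  invisible(x)
}
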