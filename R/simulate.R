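#' Synthetic genotype / correlated-score / phenotype simulation
#'
#' The simulation engine emulates the study design used to characterize
#' score combination: M causal variants in Hardy-Weinberg equilibrium
#' without LD; per-score SNP effects drawn from a multivariate normal with
#' variance h2/M on the diagonal and covariance rg * h2/M off the diagonal
#' (rg = 0.8 within the trait-specific block of scores, 0.4 elsewhere); an
#' outcome genetic value g formed as a U(0,1)-weighted combination of the
#' component genetic scores, rescaled to variance exactly h2; and
#' phenotype y = g + e with e ~ N(0, 1 - h2). GWAS effect estimation,
#' training-size sweeps and improvement slopes reproduce the
#' training-size / heritability experiments at desk scale.
#'
#' @name simulate
NULL

#' Simulation configuration
#'
#' Defaults follow the reference design: M = 1000 causal SNPs, three
#' trait-specific component scores with genetic correlation 0.8, three
#' cross-trait (pleiotropic) components with genetic correlation 0.4, and
#' 200 replicates. Sample sizes default to desk scale; `h2` may be a
#' vector, in which case sweeps run one grid row per heritability.
#'
#' @param h2 heritability (or vector of heritabilities) in `(0, 1]`
#' @param m_causal number of causal SNPs (default 1000)
#' @param n_scores_specific trait-specific component scores (default 3)
#' @param n_scores_cross cross-trait component scores (default 3)
#' @param rg_specific genetic correlation within the trait-specific block
#'   (default 0.8)
#' @param rg_cross genetic correlation involving cross-trait scores
#'   (default 0.4)
#' @param maf_range uniform range for minor-allele frequencies
#' @param n_gwas samples for per-score GWAS effect estimation
#' @param n_train_grid training-set sizes for the mixing weights
#' @param n_test held-out evaluation samples
#' @param n_replicates replicates per grid cell (default 200)
#' @param seed master seed; every replicate's seed derives from it
#' @return a `sim_config`
#' @export
sim_config <- function(h2 = 0.5, m_causal = 1000,
                       n_scores_specific = 3, n_scores_cross = 3,
                       rg_specific = 0.8, rg_cross = 0.4,
                       maf_range = c(0.01, 0.5),
                       n_gwas = 5000, n_train_grid = c(250, 1000, 4000),
                       n_test = 1500, n_replicates = 200, seed = 1) {
  stopifnot(all(h2 > 0), all(h2 <= 1), m_causal >= 1,
            n_scores_specific >= 1, n_scores_cross >= 0,
            maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2],
            n_gwas >= 1, all(n_train_grid >= 1), n_test >= 1,
            n_replicates >= 1)
  cfg <- structure(list(h2 = h2, m_causal = as.integer(m_causal),
                        n_scores_specific = as.integer(n_scores_specific),
                        n_scores_cross = as.integer(n_scores_cross),
                        rg_specific = rg_specific, rg_cross = rg_cross,
                        maf_range = maf_range, n_gwas = as.integer(n_gwas),
                        n_train_grid = as.integer(sort(n_train_grid)),
                        n_test = as.integer(n_test),
                        n_replicates = as.integer(n_replicates),
                        seed = as.integer(seed)),
                   class = "sim_config")
  invisible(effect_covariance(cfg, h2[1]))  # fail early on a non-PSD design
  cfg
}

#' Covariance matrix of the per-SNP score effects
#'
#' Diagonal `h2 / M`; off-diagonal `rg_specific * h2 / M` within the
#' trait-specific block and `rg_cross * h2 / M` for every pair involving a
#' cross-trait score.
#'
#' @param config a [sim_config()]
#' @param h2 heritability to use (defaults to the config's first)
#' @return positive semi-definite covariance matrix
#' @export
effect_covariance <- function(config, h2 = config$h2[1]) {
  k <- config$n_scores_specific + config$n_scores_cross
  v <- h2 / config$m_causal
  Sigma <- matrix(config$rg_cross * v, k, k)
  sp <- seq_len(config$n_scores_specific)
  Sigma[sp, sp] <- config$rg_specific * v
  diag(Sigma) <- v
  if (min(eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
    stop("effect covariance matrix is not positive semi-definite")
  Sigma
}

#' Simulate a genotype dosage matrix
#'
#' Per-variant minor-allele frequencies are drawn uniformly from
#' `maf_range`; each dosage is the sum of two independent allele draws,
#' so genotype frequencies follow Hardy-Weinberg proportions by
#' construction. Variants are independent (no LD).
#'
#' @param n samples
#' @param m variants
#' @param maf_range uniform MAF range (default `c(0.01, 0.5)`)
#' @param seed integer seed
#' @return a `genotype_matrix` (chromosome "1", positions `1..m`,
#'   ref "A" / alt "G" so no site is strand-ambiguous)
#' @export
simulate_genotypes <- function(n, m, maf_range = c(0.01, 0.5), seed = 1) {
  stopifnot(n >= 1, m >= 1)
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2])
    stop("maf_range must satisfy 0 < lo <= hi <= 0.5")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  maf <- stats::runif(m, maf_range[1], maf_range[2])
  D <- vapply(maf, function(p) stats::rbinom(n, 2L, p), numeric(n))
  if (n == 1) D <- matrix(D, nrow = 1)
  panel <- variant_panel(chr = "1", pos = seq_len(m), ref = "A", alt = "G")
  g <- genotype_matrix(D, panel)
  g$variants$af <- maf
  g
}

#' Draw correlated per-score SNP effects
#'
#' M independent draws from `MVN(0, Sigma)` with Sigma from
#' [effect_covariance()].
#'
#' @param config a [sim_config()]
#' @param h2 heritability (defaults to the config's first)
#' @param seed integer seed
#' @return `m_causal x n_scores` matrix of class `sim_effects` (columns
#'   `specific1..`, `cross1..`)
#' @export
simulate_effects <- function(config, h2 = config$h2[1], seed = config$seed) {
  Sigma <- effect_covariance(config, h2)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  B <- MASS::mvrnorm(config$m_causal, mu = rep(0, ncol(Sigma)),
                     Sigma = Sigma)
  colnames(B) <- c(paste0("specific", seq_len(config$n_scores_specific)),
                   if (config$n_scores_cross > 0)
                     paste0("cross", seq_len(config$n_scores_cross)))
  class(B) <- c("sim_effects", class(B))
  B
}

# per-sample component genetic scores on centered dosages
.component_scores <- function(dosages, effects) {
  Xc <- scale(dosages, center = TRUE, scale = FALSE)
  Xc %*% effects
}

# rescale a raw genetic value to variance exactly h2
.rescale_g <- function(g_raw, h2) {
  s <- stats::sd(g_raw)
  if (s == 0) stop("degenerate genetic component (zero variance)")
  as.numeric(scale(g_raw)) * sqrt(h2)
}

#' Simulate an outcome phenotype from component scores
#'
#' The outcome genetic value is a U(0,1)-weighted combination of the
#' per-sample component genetic scores, standardized and rescaled to
#' variance exactly `h2` (so that `e ~ N(0, 1 - h2)` yields a
#' unit-variance phenotype); then `y = g + e`. With `h2 = 1`, `y = g`
#' exactly.
#'
#' @param genotypes a `genotype_matrix` (or plain dosage matrix)
#' @param effects a `sim_effects` matrix
#' @param h2 heritability in `(0, 1]`
#' @param seed integer seed (drives the combination weights and the noise)
#' @param weights optional fixed combination weights (length = number of
#'   scores); drawn from U(0,1) when `NULL`
#' @return list with `y`, `g` (variance exactly h2), `weights` and
#'   `components` (samples x scores matrix of component genetic values)
#' @export
simulate_phenotype <- function(genotypes, effects, h2, seed = 1,
                               weights = NULL) {
  stopifnot(h2 > 0, h2 <= 1)
  D <- if (inherits(genotypes, "genotype_matrix")) genotypes$dosages
       else as.matrix(genotypes)
  stopifnot(ncol(D) == nrow(effects))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  comp <- .component_scores(D, effects)
  if (is.null(weights)) weights <- stats::runif(ncol(comp))
  g <- .rescale_g(drop(comp %*% weights), h2)
  e <- if (h2 < 1) stats::rnorm(nrow(D), 0, sqrt(1 - h2)) else 0
  list(y = g + e, g = g, weights = weights, components = comp)
}

# vectorized per-variant marginal least squares of y on centered dosage
.marginal_gwas <- function(X, y) {
  n <- length(y)
  xc <- scale(X, center = TRUE, scale = FALSE)
  yc <- y - mean(y)
  sxx <- colSums(xc^2)
  mono <- sxx == 0
  sxx[mono] <- NA_real_
  beta <- drop(crossprod(xc, yc)) / sxx
  sse <- sum(yc^2) - beta^2 * sxx
  se <- sqrt(pmax(sse, 0) / (n - 2) / sxx)
  tstat <- beta / se
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  data.frame(beta = beta, se = se, p = p, monomorphic = mono)
}

#' Per-SNP marginal association scan
#'
#' Simple linear regression of the phenotype on each variant's centered
#' dosage: the per-variant slope, its standard error and p-value.
#' Monomorphic variants are flagged and returned as missing.
#'
#' @param genotypes a `genotype_matrix`
#' @param phenotype numeric phenotype vector
#' @return data frame: chr, pos, ref, alt, beta, se, p, monomorphic
#' @export
run_gwas <- function(genotypes, phenotype) {
  stopifnot(inherits(genotypes, "genotype_matrix"),
            length(phenotype) == length(genotypes$sample_ids),
            length(phenotype) > 3)
  res <- .marginal_gwas(genotypes$dosages, phenotype)
  cbind(genotypes$variants[, c("chr", "pos", "ref", "alt")], res)
}

#' Turn GWAS estimates into a harmonized scoring
#'
#' Uses the estimated per-SNP slopes directly as per-alt-allele score
#' weights (no LD pruning is needed for LD-free simulated genotypes).
#'
#' @param gwas data frame from [run_gwas()]
#' @param score_id identifier for the resulting score
#' @param trait_label optional trait label
#' @return a `harmonized_scoring`
#' @export
gwas_to_scoring <- function(gwas, score_id, trait_label = NA_character_) {
  keep <- !gwas$monomorphic & is.finite(gwas$beta)
  structure(list(score_id = score_id, trait_label = trait_label,
                 records = data.frame(chr = gwas$chr[keep],
                                      pos = gwas$pos[keep],
                                      ref = gwas$ref[keep],
                                      alt = gwas$alt[keep],
                                      weight = gwas$beta[keep],
                                      stringsAsFactors = FALSE),
                 n_flipped = 0L, n_dropped = sum(!keep)),
            class = "harmonized_scoring")
}

# one replicate of the training-size sweep; returns a long data frame of
# fold-ratios per (n_train, method)
.sweep_replicate <- function(config, h2, seed, mix_alpha, nfolds) {
  k_sp <- config$n_scores_specific
  k <- k_sp + config$n_scores_cross
  n_pool <- max(config$n_train_grid)
  n_tot <- config$n_gwas + n_pool + config$n_test

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1, 5)

  geno <- simulate_genotypes(n_tot, config$m_causal, config$maf_range,
                             seed = seeds[1])
  D <- geno$dosages
  B <- simulate_effects(config, h2, seed = seeds[2])

  i_gwas <- seq_len(config$n_gwas)
  i_pool <- config$n_gwas + seq_len(n_pool)
  i_test <- config$n_gwas + n_pool + seq_len(config$n_test)

  # per-component GWAS on the GWAS set, each trait with heritability h2
  Dg <- D[i_gwas, , drop = FALSE]
  comp_g <- .component_scores(Dg, B)
  Bhat <- matrix(0, config$m_causal, k)
  set.seed(seeds[3])
  for (i in seq_len(k)) {
    gi <- .rescale_g(comp_g[, i], h2)
    yi <- gi + stats::rnorm(length(gi), 0, sqrt(1 - h2))
    Bhat[, i] <- .marginal_gwas(Dg, yi)$beta
  }
  Bhat[is.na(Bhat)] <- 0

  # estimated single scores for the train pool and test set
  i_eval <- c(i_pool, i_test)
  S <- D[i_eval, , drop = FALSE] %*% Bhat
  colnames(S) <- colnames(B)

  # outcome phenotype on the evaluation samples
  ph <- simulate_phenotype(D[i_eval, , drop = FALSE], B, h2,
                           seed = seeds[4])
  y <- ph$y
  pool_rows <- seq_len(n_pool)
  test_rows <- n_pool + seq_len(config$n_test)

  # baseline: the replicate's best-performing trait-specific single score,
  # identified on the full training pool (so the reference does not vary
  # with the mixing training size) and evaluated on the held-out test set
  pool_r2 <- vapply(seq_len(k_sp), function(i)
    stats::cor(S[pool_rows, i], y[pool_rows])^2, 0)
  best <- which.max(pool_r2)
  r2_best <- stats::cor(S[test_rows, best], y[test_rows])^2

  out <- list()
  for (n_train in config$n_train_grid) {
    tr <- pool_rows[seq_len(n_train)]
    for (method in c("prsmix", "prsmix_plus")) {
      cols <- if (method == "prsmix") seq_len(k_sp) else seq_len(k)
      w <- fit_mixture(S[tr, cols, drop = FALSE], y[tr],
                       family = "continuous", mix_alpha = mix_alpha,
                       nfolds = nfolds, seed = seeds[5])
      r2_mix <- if (w$informative)
        stats::cor(combine_scores(w, S[test_rows, cols, drop = FALSE]),
                   y[test_rows])^2 else NA_real_
      out[[length(out) + 1]] <- data.frame(
        h2 = h2, n_train = n_train, method = method,
        r2_combined = r2_mix, r2_best_single = r2_best,
        fold_ratio = r2_mix / r2_best)
    }
  }
  do.call(rbind, out)
}

#' Training-size sweep of the combination improvement
#'
#' For every replicate: simulate genotypes and correlated SNP effects,
#' run a per-component GWAS on a dedicated GWAS set, build single scores
#' from the estimated effects, fit the trait-specific mixture (the
#' trait-specific components) and the cross-trait mixture (all
#' components) on each training size, and evaluate the fold-ratio of
#' test-set R2 against the best-performing single score (chosen on the
#' training split) on a fixed test set. GWAS, training and test samples
#' are pairwise disjoint within each replicate.
#'
#' @param config a [sim_config()]; `config$h2` may be a vector
#' @param mix_alpha,nfolds passed to [fit_mixture()]
#' @return a `sweep_result`: `cells` (h2, n_train, method, mean
#'   fold-ratio, normal-theory 95% CI, n_replicates) and `replicates`
#'   (per-replicate fold-ratios)
#' @export
sweep_training_sizes <- function(config, mix_alpha = 0.5, nfolds = 5) {
  stopifnot(inherits(config, "sim_config"),
            length(config$n_train_grid) >= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  seeds <- matrix(sample.int(.Machine$integer.max - 1,
                             length(config$h2) * config$n_replicates),
                  nrow = config$n_replicates)
  reps <- list()
  for (j in seq_along(config$h2)) {
    for (r in seq_len(config$n_replicates)) {
      df <- .sweep_replicate(config, config$h2[j], seeds[r, j],
                             mix_alpha, nfolds)
      df$replicate <- r
      reps[[length(reps) + 1]] <- df
    }
  }
  replicates <- do.call(rbind, reps)
  agg <- stats::aggregate(fold_ratio ~ h2 + n_train + method, replicates,
                          function(x) c(mean = mean(x), sd = stats::sd(x),
                                        n = length(x)))
  cells <- cbind(agg[, c("h2", "n_train", "method")],
                 as.data.frame(agg$fold_ratio))
  half <- stats::qt(0.975, pmax(cells$n - 1, 1)) * cells$sd / sqrt(cells$n)
  cells$mean_ratio <- cells$mean
  cells$ci_lo <- cells$mean - half
  cells$ci_hi <- cells$mean + half
  cells$n_replicates <- cells$n
  cells <- cells[order(cells$h2, cells$method, cells$n_train),
                 c("h2", "n_train", "method", "mean_ratio", "ci_lo",
                   "ci_hi", "n_replicates")]
  rownames(cells) <- NULL
  structure(list(cells = cells, replicates = replicates, config = config),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("<sweep_result>\n")
  print(x$cells, digits = 4)
  invisible(x)
}

#' Improvement slope per log10 of training size
#'
#' Least-squares slope of the mean fold-ratio on `log10(n_train)`, per
#' heritability level and method: the gain in relative accuracy per
#' ten-fold increase of the training sample.
#'
#' @param sweep a `sweep_result`
#' @return data frame: h2, method, slope
#' @export
improvement_slope <- function(sweep) {
  cells <- if (inherits(sweep, "sweep_result")) sweep$cells else sweep
  out <- list()
  for (h in unique(cells$h2)) for (m in unique(cells$method)) {
    d <- cells[cells$h2 == h & cells$method == m, ]
    if (nrow(d) == 0) next
    if (length(unique(d$n_train)) < 2)
      stop("need at least two training sizes per heritability level")
    fit <- stats::lm(mean_ratio ~ log10(n_train), data = d)
    out[[length(out) + 1]] <- data.frame(h2 = h, method = m,
                                         slope = unname(stats::coef(fit)[2]))
  }
  do.call(rbind, out)
}
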