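test_that("category-free NRI matches hand counts and its bounds", {
  # 4 cases: 3 up, 1 down; 4 controls: 3 down, 1 up -> NRI = 0.5 + 0.5 = 1
  base <- rep(0.5, 8)
  aug <- c(0.6, 0.7, 0.8, 0.4, 0.3, 0.2, 0.1, 0.9)
  y <- c(1, 1, 1, 1, 0, 0, 0, 0)
  res <- category_free_nri(risk_model_pair(base, aug, y), n_bootstrap = 50,
                           seed = 1)
  expect_equal(res$nri_cases, 0.5)
  expect_equal(res$nri_controls, 0.5)
  expect_equal(res$nri_total, 1.0)

  # identity models: zero everywhere, ties counted as neither direction
  id <- category_free_nri(risk_model_pair(base, base, y), n_bootstrap = 20,
                          seed = 1)
  expect_equal(id$nri_total, 0)
  expect_equal(id$n_ties, 8L)

  # formula maximum: every case up, every control down
  mx <- category_free_nri(
    risk_model_pair(rep(0.5, 8), c(rep(0.9, 4), rep(0.1, 4)), y),
    n_bootstrap = 20, seed = 1)
  expect_equal(mx$nri_total, 2)

  expect_error(category_free_nri(risk_model_pair(base, aug, rep(1, 8))),
               "single class")
})

test_that("NRI is antisymmetric and bootstrap CIs behave", {
  set.seed(61)
  n <- 400
  y <- rbinom(n, 1, 0.3)
  base <- plogis(rnorm(n))
  aug <- plogis(rnorm(n) + y)
  fwd <- category_free_nri(risk_model_pair(base, aug, y), 200, seed = 3)
  rev <- category_free_nri(risk_model_pair(aug, base, y), 200, seed = 3)
  expect_equal(rev$nri_total, -fwd$nri_total)
  expect_true(fwd$nri_cases >= -1 && fwd$nri_cases <= 1)
  expect_true(fwd$nri_total >= -2 && fwd$nri_total <= 2)
  expect_true(fwd$ci95[1] <= fwd$nri_total && fwd$nri_total <= fwd$ci95[2])

  # CI width shrinks with sample size
  big <- category_free_nri(
    risk_model_pair(rep(base, 4), rep(aug, 4), rep(y, 4)), 200, seed = 3)
  expect_lt(diff(big$ci95), diff(fwd$ci95))
})

test_that("rank AUC matches all-pairs enumeration and monotone invariance", {
  pred <- c(0.1, 0.4, 0.35, 0.8, 0.6, 0.6)
  y <- c(0, 0, 1, 1, 0, 1)
  # brute force over all case-control pairs, ties counted one half
  cases <- which(y == 1); controls <- which(y == 0)
  pairs <- expand.grid(cases, controls)
  conc <- mean(ifelse(pred[pairs[, 1]] > pred[pairs[, 2]], 1,
                      ifelse(pred[pairs[, 1]] == pred[pairs[, 2]], 0.5, 0)))
  expect_equal(rank_auc(pred, y), conc)
  expect_equal(rank_auc(qlogis(pred), y), conc)   # monotone transform
})

test_that("incremental AUC has forced endpoints and enumerated values", {
  y <- c(1, 1, 1, 0, 0, 0)
  pair <- risk_model_pair(rep(0.5, 6), c(0.9, 0.8, 0.7, 0.1, 0.2, 0.3), y)
  res <- incremental_auc(pair, n_bootstrap = 30, seed = 2)
  expect_equal(res$auc_baseline, 0.5)
  expect_equal(res$auc_augmented, 1)
  expect_equal(res$delta_auc, 0.5)

  same <- incremental_auc(risk_model_pair(rep(0.5, 6), rep(0.5, 6), y),
                          n_bootstrap = 10, seed = 2)
  expect_equal(same$delta_auc, 0)

  pred <- c(0.15, 0.4, 0.35, 0.8, 0.6, 0.6)
  pair2 <- risk_model_pair(rep(0.5, 6), pred, y)
  res2 <- incremental_auc(pair2, n_bootstrap = 10, seed = 2)
  expect_equal(res2$delta_auc, rank_auc(pred, y) - 0.5)
})

test_that("odds ratio per SD is scale-invariant and recovers planted effects", {
  set.seed(63)
  n <- 6000
  s <- rnorm(n, 5, 3)
  y <- rbinom(n, 1, plogis(-1 + 0.5 * scale(s)))
  r1 <- or_per_sd(s, y)
  r2 <- or_per_sd(2 * s, y)      # doubling the scale changes nothing
  expect_equal(r1$or, r2$or, tolerance = 1e-10)
  expect_true(r1$or > exp(0.5) * 0.85 && r1$or < exp(0.5) * 1.15)
  expect_true(r1$ci95[1] < r1$or && r1$or < r1$ci95[2])
})

test_that("top-decile OR matches the 2x2 cross-product on a constructed table", {
  # top decile: 20 cases / 80 controls; remainder: 90 cases / 810 controls
  n <- 1000
  score <- c(seq(2, 3, length.out = 100), seq(0, 1, length.out = 900))
  y <- c(rep(1, 20), rep(0, 80), rep(1, 90), rep(0, 810))
  res <- top_decile_or(score, y)
  expect_equal(res$n_top, 100L)
  expect_equal(res$or, (20 * 810) / (80 * 90), tolerance = 1e-6)

  # uninformative score: OR near 1 on average
  set.seed(64)
  ors <- replicate(20, {
    s <- rnorm(800); yy <- rbinom(800, 1, 0.3)
    top_decile_or(s, yy)$or
  })
  expect_equal(mean(ors), 1, tolerance = 0.1)

  # perfect concentration of cases in the top decile is flagged separation
  s2 <- c(rep(2, 100), rep(0, 900))
  y2 <- c(rep(1, 100), rep(0, 900))
  s2 <- s2 + seq_len(1000) * 1e-6    # break ties so the top group is exact
  suppressWarnings(expect_error(top_decile_or(s2, y2), "separation"))
})

test_that("association scans apply Bonferroni across tested columns", {
  set.seed(65)
  n <- 1500
  s <- rnorm(n)
  P <- cbind(null1 = rbinom(n, 1, 0.2),
             null2 = rbinom(n, 1, 0.4),
             hit = rbinom(n, 1, plogis(-1.5 + 0.8 * s)),
             flat = rep(0, n))
  expect_warning(res <- assoc_scan(s, P), "flat")
  expect_equal(res$n_tested, 3L)
  expect_equal(res$bonferroni, 0.05 / 3)
  tab <- res$results
  expect_true(tab$significant[tab$phenotype == "hit"])
  expect_false(any(tab$significant[tab$phenotype %in% c("null1", "null2")]))
  expect_equal(res$skipped, "flat")
})

test_that("family-wise error is controlled on all-null phenotype matrices", {
  set.seed(66)
  hits <- vapply(1:10, function(r) {
    n <- 400
    s <- rnorm(n)
    P <- matrix(rbinom(n * 50, 1, 0.3), n)
    sum(assoc_scan(s, P)$results$significant)
  }, 0)
  expect_gte(mean(hits == 0), 0.9)
})

test_that("fit_risk_models produces a usable baseline/augmented pair", {
  set.seed(67)
  n <- 800
  covars <- cbind(age = rnorm(n), sex = rbinom(n, 1, 0.5))
  s <- rnorm(n)
  y <- rbinom(n, 1, plogis(-1 + 0.6 * s + 0.3 * covars[, 1]))
  pair <- fit_risk_models(s, y, covars)
  expect_s3_class(pair, "risk_model_pair")
  expect_gt(incremental_auc(pair, 20, seed = 1)$delta_auc, 0)
  expect_gt(category_free_nri(pair, 20, seed = 1)$nri_total, 0)
})
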