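test_that("splits are disjoint, exhaustive, deterministic and stratified", {
  ids <- paste0("s", 1:100)
  sp <- split_samples(ids, spec = split_spec(seed = 5))
  expect_equal(length(sp$train), 80)
  expect_equal(length(sp$test), 20)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), ids)
  expect_identical(sp, split_samples(ids, spec = split_spec(seed = 5)))
  expect_false(identical(sp, split_samples(ids, spec = split_spec(seed = 6))))

  # stratified split preserves prevalence within a sample per stratum
  y <- rep(c(1, 0), c(100, 900))
  ids2 <- paste0("t", 1:1000)
  sp2 <- split_samples(ids2, y, split_spec(seed = 1))
  prev_train <- mean(y[match(sp2$train, ids2)])
  prev_test <- mean(y[match(sp2$test, ids2)])
  expect_true(prev_train >= 0.09 && prev_train <= 0.11)
  expect_true(prev_test >= 0.09 && prev_test <= 0.11)

  y_rare <- rep(c(1, 0), c(1, 99))
  expect_error(split_samples(paste0("u", 1:100), y_rare, split_spec()),
               "stratum")
})

test_that("a single-score mixture is a rescaling of that score", {
  set.seed(41)
  n <- 500
  s <- rnorm(n)
  y <- 0.7 * s + rnorm(n)
  w <- fit_mixture(cbind(only = s), y, family = "continuous", seed = 2)
  expect_equal(w$score_ids, "only")
  combined <- combine_scores(w, cbind(only = s))
  expect_equal(cor(combined, s, method = "spearman"), 1)
  expect_equal(cor(combined, y)^2, cor(s, y)^2, tolerance = 1e-6)
  expect_equal(w$alpha_adj, w$omega / w$sigma, ignore_attr = TRUE)
})

test_that("mixture weights recover known generative proportions", {
  ratios <- vapply(1:8, function(r) {
    set.seed(400 + r)
    n <- 5000
    z1 <- rnorm(n); z2 <- rnorm(n)
    y <- 0.6 * z1 + 0.4 * z2 + rnorm(n, 0, sqrt(1 - 0.36 - 0.16))
    w <- fit_mixture(cbind(a = z1, b = z2), y, family = "continuous",
                     seed = r)
    w$alpha_adj[1] / w$alpha_adj[2]
  }, 0)
  expect_gt(mean(ratios), 1.2)
  expect_lt(mean(ratios), 1.9)
})

test_that("null outcomes shrink the mixing weights toward zero", {
  shrunk <- vapply(1:10, function(r) {
    set.seed(500 + r)
    n <- 2000
    S <- matrix(rnorm(n * 10), n)
    colnames(S) <- paste0("s", 1:10)
    y <- rnorm(n)
    w <- fit_mixture(S, y, family = "continuous", seed = r)
    all(abs(w$omega) <= 0.05)
  }, TRUE)
  expect_gte(mean(shrunk), 0.9)
})

test_that("zero-variance scores and single-class CV folds are errors", {
  n <- 100
  S <- cbind(a = rnorm(n), b = rep(2, n))
  expect_error(fit_mixture(S, rnorm(n), family = "continuous"), "b")
  y_rare <- c(1, rep(0, n - 1))
  expect_error(fit_mixture(cbind(a = rnorm(n), c = rnorm(n)), y_rare,
                           family = "binary"), "single")
})

test_that("derived SNP effects reproduce the score-level combination", {
  set.seed(43)
  g <- simulate_genotypes(200, 50, seed = 6)
  # three scores over overlapping variant subsets
  idx <- list(1:30, 15:45, c(1:10, 40:50))
  scorings <- lapply(1:3, function(i) {
    v <- g$variants[idx[[i]], ]
    structure(list(score_id = paste0("s", i), trait_label = "height",
                   records = data.frame(chr = v$chr, pos = v$pos,
                                        ref = v$ref, alt = v$alt,
                                        weight = rnorm(nrow(v)),
                                        stringsAsFactors = FALSE),
                   n_flipped = 0L, n_dropped = 0L),
              class = "harmonized_scoring")
  })
  pan <- build_panel(g, scorings)
  y <- rowSums(pan$values) + rnorm(200, 0, 2)
  w <- fit_mixture(pan, y, family = "continuous", seed = 3)
  eff <- derive_snp_effects(w, scorings)
  expect_equal(nrow(eff$variants), 50)   # union of the three subsets

  # identity case: single score with alpha 1
  w1 <- w; w1$score_ids <- "s1"; w1$alpha_adj <- 1
  e1 <- derive_snp_effects(w1, scorings)
  expect_equal(unname(e1$gamma), scorings[[1]]$records$weight)

  # a variant present in one score only contributes alpha * beta
  v1only <- setdiff(idx[[1]], union(idx[[2]], idx[[3]]))[1]
  key <- variant_key("1", v1only, "A", "G")
  beta <- scorings[[1]]$records$weight[match(v1only, scorings[[1]]$records$pos)]
  expect_equal(unname(eff$gamma[key]), unname(w$alpha_adj[1] * beta))

  # SNP-level scoring equals the score-level mixture
  lhs <- compute_prs(g, as_harmonized_scoring(eff))
  rhs <- combine_scores(w, pan)
  expect_lt(max(abs(lhs - rhs)), 1e-8)

  expect_error(derive_snp_effects(w, scorings[1:2]), "s3")
})

test_that("trait-specific combination filters by label and beats noise components", {
  fx <- fixture_sim(n = 1200, m = 40, h2 = 0.6, seed = 71)
  g <- fx$genotypes
  comp <- fx$pheno$components
  set.seed(72)
  scorings <- list(
    make_harmonized(g$variants, fx$effects[, 1] + rnorm(40, 0, 0.02),
                    score_id = "good1", trait = "Height"),
    make_harmonized(g$variants, fx$effects[, 2] + rnorm(40, 0, 0.02),
                    score_id = "good2", trait = "height"),
    make_harmonized(g$variants, rnorm(40, 0, 0.05),
                    score_id = "noise", trait = "HEIGHT"),
    make_harmonized(g$variants, fx$effects[, 4], score_id = "other",
                    trait = "bmi")
  )
  pan <- build_panel(g, scorings)
  y <- fx$pheno$y
  res <- prsmix(pan, "Height", y, family = "continuous",
                spec = split_spec(seed = 9), rule = NULL,
                scorings = scorings)
  # case-normalized matching co-selects all three height-labelled scores
  expect_setequal(res$retained, c("good1", "good2", "noise"))
  # the pure-noise component gets a negligible standardized weight
  o <- abs(setNames(res$weights$omega, res$weights$score_ids))
  expect_lt(o["noise"], 0.2 * max(o))
  expect_s3_class(res$test_accuracy, "accuracy_estimate")
  expect_s3_class(res$effects, "adjusted_effects")
  expect_error(prsmix(pan, "glucose", y, family = "continuous"),
               "no candidate")
})

test_that("the cross-trait combination includes other-trait scores", {
  fx <- fixture_sim(n = 1500, m = 40, h2 = 0.6, seed = 81)
  g <- fx$genotypes
  set.seed(82)
  scorings <- list(
    make_harmonized(g$variants, fx$effects[, 1], "spec1", "height"),
    make_harmonized(g$variants, fx$effects[, 2], "spec2", "height"),
    make_harmonized(g$variants, fx$effects[, 4], "cross1", "bmi")
  )
  pan <- build_panel(g, scorings)
  y <- fx$pheno$y
  spec <- split_spec(seed = 4)
  res_mix <- prsmix(pan, "height", y, family = "continuous", spec = spec,
                    rule = NULL)
  res_plus <- prsmix_plus(pan, y, family = "continuous", spec = spec,
                          rule = NULL)
  expect_setequal(res_plus$retained, c("spec1", "spec2", "cross1"))
  expect_setequal(res_mix$retained, c("spec1", "spec2"))
  # with only outcome-trait scores in the panel, the two methods coincide
  pan2 <- score_panel(pan$values[, 1:2],
                      meta = pan$meta[1:2, ], sample_ids = pan$sample_ids)
  r1 <- prsmix(pan2, "height", y, family = "continuous", spec = spec,
               rule = NULL)
  r2 <- prsmix_plus(pan2, y, family = "continuous", spec = spec,
                    rule = NULL)
  expect_equal(r1$weights$alpha_adj, r2$weights$alpha_adj)
  expect_equal(r1$test_accuracy$r2, r2$test_accuracy$r2)
})

test_that("mixture results are invariant to the order of input scorings", {
  fx <- fixture_sim(n = 800, m = 30, h2 = 0.5, seed = 91)
  g <- fx$genotypes
  scorings <- lapply(1:3, function(i)
    make_harmonized(g$variants, fx$effects[, i], paste0("s", i), "height"))
  y <- fx$pheno$y
  spec <- split_spec(seed = 11)
  r_fwd <- prsmix(build_panel(g, scorings), "height", y,
                  family = "continuous", spec = spec, rule = NULL)
  r_rev <- prsmix(build_panel(g, rev(scorings)), "height", y,
                  family = "continuous", spec = spec, rule = NULL)
  a_fwd <- setNames(r_fwd$weights$alpha_adj, r_fwd$weights$score_ids)
  a_rev <- setNames(r_rev$weights$alpha_adj, r_rev$weights$score_ids)
  expect_equal(a_fwd, a_rev[names(a_fwd)], tolerance = 1e-3)
  expect_equal(r_fwd$test_accuracy$r2, r_rev$test_accuracy$r2,
               tolerance = 1e-4)
})

test_that("improvement_test reproduces the textbook one-sample t-test", {
  r <- improvement_test(c(1.1, 1.2, 1.3), c(1, 1, 1))
  expect_equal(r$fold_ratios, c(1.1, 1.2, 1.3))
  expect_equal(r$mean_ratio, 1.2)
  # independent oracle: t = (mean - 1) / (sd / sqrt(k))
  tstat <- (1.2 - 1) / (sd(c(1.1, 1.2, 1.3)) / sqrt(3))
  expect_equal(r$p_value, 2 * pt(-abs(tstat), df = 2))
  expect_equal(r$ci95[1], 1.2 - qt(0.975, 2) * 0.1 / sqrt(3))

  # scale invariance of the ratios
  r2 <- improvement_test(10 * c(1.1, 1.2, 1.3), 10 * c(1, 1, 1))
  expect_equal(r2$fold_ratios, r$fold_ratios)

  # degenerate: identical vectors
  rd <- improvement_test(c(0.2, 0.3), c(0.2, 0.3))
  expect_equal(rd$mean_ratio, 1)
  expect_equal(rd$p_value, 1)
  expect_error(improvement_test(c(0.1, -0.2), c(0.1, 0.1)), "positive")
})
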