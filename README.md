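# scoremix

Combining published polygenic scores into a single, better one.

## The problem

The PGS Catalog holds thousands of published polygenic scores (PGS), with
many scores per trait, each estimated in a different cohort with a
different method. Any single score leaves signal on the table — both
signal captured by *other scores for the same trait* and signal carried by
scores for *genetically correlated traits* through pleiotropy. `scoremix`
is for statistical geneticists and clinical researchers who have a target
cohort (genotype dosages + phenotypes) and a collection of scoring files,
and want one score per trait that uses all of it.

## What it does

1. **Harmonize** (`parse_scoring_file()`, `harmonize()`): re-express every
   published per-allele weight per copy of the target panel's alternative
   allele, flipping signs where the effect allele is the reference and
   dropping unmatched, multi-allelic and strand-ambiguous (A/T, C/G)
   variants, with counts of everything flipped or dropped.
2. **Score** (`compute_prs()`, `build_panel()`): PRS\_*ni* = Σ\_*j*
   *d\_nj* β\_*ji* over a dosage matrix, giving a samples × scores panel.
3. **Filter** (`evaluate_panel()`, `select_high_power()`): keep scores
   with analytic power > 0.95 and p ≤ 0.05 on the training split, where
   power comes from the non-centrality parameter λ = N·R²/(1−R²) and the
   two-sided normal approximation
   1 − Φ(z₁₋α/₂ − √λ) + Φ(zα/₂ − √λ). Accuracy is partial R² over
   covariates (continuous traits) or liability-scale R² via the
   K(1−K)/z² transformation (binary traits).
4. **Mix** (`prsmix()`, `prsmix_plus()`, `fit_mixture()`): elastic-net fit
   of the trait on the standardized retained scores (5-fold CV penalty,
   unpenalized covariates). `prsmix()` restricts candidates to the outcome
   trait's own scores; `prsmix_plus()` admits every high-power score.
   Mixing weights ω̂ᵢ are back-adjusted to raw-score scale,
   α̂ᵢ = ω̂ᵢ/σᵢ, and the combined score's exact per-allele effects
   γ̂ⱼ = Σᵢ α̂ᵢ βⱼᵢ are materialized (`derive_snp_effects()`) and written
   as a new scoring file (`write_scoring_file()`).
5. **Evaluate** (`improvement_test()`, `category_free_nri()`,
   `incremental_auc()`, `or_per_sd()`, `top_decile_or()`, `assoc_scan()`):
   fold-ratio of test-set R² against the best single score (selected on
   training data only), category-free net reclassification improvement
   with bootstrap CIs, incremental AUC, odds ratios, and a phenome-style
   association scan with Bonferroni correction.
6. **Simulate** (`simulate_genotypes()`, `simulate_effects()`,
   `simulate_phenotype()`, `run_gwas()`, `sweep_training_sizes()`,
   `improvement_slope()`): a synthetic-data engine with block-correlated
   per-SNP effects (r\_g = 0.8 within trait-specific scores, 0.4 across
   traits), used for the training-size / heritability experiments and as
   the test-data source for the whole package.

## Worked example

Six "published" scores are built by GWAS re-estimation on independent
synthetic cohorts — three for the outcome trait, three for a correlated
trait — then combined in a 2,000-sample target cohort:

```r
library(scoremix)
cfg <- sim_config(h2 = 0.5, m_causal = 150, seed = 2024)
geno <- simulate_genotypes(2000, 150, seed = 1)
effects <- simulate_effects(cfg, seed = 2)
pheno <- simulate_phenotype(geno, effects, h2 = 0.5, seed = 3)

scorings <- lapply(1:6, function(i) {
  gwas_cohort <- simulate_genotypes(3000, 150, seed = 10 + i)
  gi <- simulate_phenotype(gwas_cohort, effects[, i, drop = FALSE],
                           h2 = 0.5, seed = 20 + i, weights = 1)
  gwas_to_scoring(run_gwas(gwas_cohort, gi$y),
                  score_id = sprintf("PGS%03d", i),
                  trait_label = if (i <= 3) "height" else "correlated")
})

panel <- build_panel(geno, scorings)
res <- prsmix(panel, "height", pheno$y, family = "continuous",
              spec = split_spec(seed = 7), scorings = scorings)
res
#> <prs_mix_result> 3 scores mixed; test R2 = 0.3753; best single ('PGS003') R2 = 0.3075; fold-ratio = 1.221
res$weights
#> <mix_weights> 3 scores (3 non-zero), family = continuous
#>        score_id      omega     sigma alpha_adj
#> PGS001   PGS001 0.08387061 0.7451043 0.1125622
#> PGS002   PGS002 0.29040814 0.7181541 0.4043814
#> PGS003   PGS003 0.30501081 0.7852249 0.3884375

prsmix_plus(panel, pheno$y, family = "continuous", spec = split_spec(seed = 7))
#> <prs_mix_result> 6 scores mixed; test R2 = 0.4342; best single ('PGS003') R2 = 0.3075; fold-ratio = 1.412
```

Reading this: the trait-specific mixture of three height scores explains
37.5% of phenotypic variance on the held-out 20% test split, a 1.22-fold
improvement over the best single score (itself chosen on the training
split); admitting the three correlated-trait scores lifts this to 43.4%
(1.41-fold). The `alpha_adj` column contains the raw-scale mixing weights
α̂ᵢ, and `res$effects` holds the combined per-allele effects γ̂ⱼ, writable
with `write_scoring_file(res$effects, "combined.txt")` and usable like any
other scoring file.

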