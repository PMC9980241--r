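---
title: "Combining polygenic scores: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Combining polygenic scores: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(scoremix)
```

## The problem

Hundreds of polygenic scores (PGS) have been published for the same traits,
each a table of per-variant effect sizes estimated in a different cohort
with a different method. No single score captures all of the available
signal, and scores for genetically correlated traits carry additional,
partly independent information through pleiotropy. `scoremix` combines many
published scores into one: a *trait-specific* combination restricted to
scores of the outcome trait, and a *cross-trait* combination that admits
every well-powered score in the collection.

## The model

For individual $n$, score $i$ is the weighted allele count
$\mathrm{PRS}_{ni} = \sum_j d_{nj}\,\beta_{ji}$, where $d_{nj} \in [0,2]$ is
the dosage of the panel's alternative allele at variant $j$ and
$\beta_{ji}$ the published per-allele effect, harmonized to the panel's
allele convention. The combination is a penalized linear model on
standardized scores:

$$ y \sim \omega_0 + \sum_i \omega_i Z_i + \text{covariates}, \qquad
   Z_i = (\mathrm{PRS}_i - \mu_i)/\sigma_i, $$

fitted by elastic net with the penalty strength chosen by 5-fold
cross-validation; covariates (age, sex, principal components) are included
unpenalized. The mixing weights are mapped back to the raw-score scale as
$\hat\alpha_i = \hat\omega_i / \sigma_i$, with $\mu_i,\sigma_i$ frozen from
the training split. Because each score is itself linear in dosages, the
combined score has exact per-allele effects

$$ \hat\gamma_j = \sum_i \hat\alpha_i\,\beta_{ji},
   \qquad \beta_{ji} = 0 \text{ when variant } j \notin \text{score } i, $$

which `derive_snp_effects()` materializes and `write_scoring_file()` saves
as a new scoring file. This identity (score-level mixture equals SNP-level
re-scoring) is asserted to 1e-8 in the test suite and is the main
correctness anchor of the pipeline.

## Filtering candidates by power

Before fitting, each candidate score is evaluated on the training split.
Accuracy is the partial $R^2$ over covariates for continuous traits; for
binary traits the observed-scale $R^2$ from a linear probability model is
transformed to the liability scale by the factor $K(1-K)/z^2$ ($z$ the
standard normal density at the $K$-quantile, $K$ the prevalence,
approximated by the sample prevalence by default; the full two-prevalence
form is available through the `prevalence` argument). The association test's
non-centrality parameter is $\lambda = N R^2 / (1 - R^2)$ and its two-sided
power at level $\alpha$ is

$$ 1 - \Phi(z_{1-\alpha/2} - \sqrt\lambda) + \Phi(z_{\alpha/2} - \sqrt\lambda). $$

Scores with power $> 0.95$ and $p \le 0.05$ are retained
(`selection_rule()`; a Bonferroni level such as $0.05/2600$ may be supplied
instead — the per-trait 0.05 default is the more permissive of the two
conventions and is logged in the retention table). The theoretical
standard error of $R^2$,
$\operatorname{var}(R^2) = 4R^2(1-R^2)^2(N-2)^2 / ((N^2-1)(N+3))$, gives
analytic confidence intervals for accuracy. Both the power formula and the
$R^2$ variance are validated against Monte-Carlo oracles in
`tests/testthat/test-acceptance.R` (rejection rates within $\pm 0.02$ at
10,000 replicates; empirical SD within 10% at 5,000 replicates).

A note on the power formula: some presentations of it confuse the normal
and chi-square forms. The implementation uses the standard two-sided
normal approximation with $\sqrt\lambda$, which agrees with the
non-central $\chi^2_1(\lambda)$ tail formulation to about $10^{-3}$ and
with simulated rejection rates; the chi-square cross-check is part of the
unit tests.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `train_fraction` | 0.8 | fraction of the cohort used to learn mixing weights |
| `power_threshold` | 0.95 | retention threshold on analytic power |
| `p_threshold` | 0.05 | retention threshold on the association p-value |
| `mix_alpha` | 0.5 | elastic-net L1/L2 balance |
| `nfolds` | 5 | cross-validation folds for the penalty strength |
| `keep_ambiguous` | `FALSE` | retain palindromic (A/T, C/G) variants |

The elastic-net balance deserves a comment: "default parameters" is
underdetermined, because different software defaults differ. We fix the
L1 ratio at 0.5 — an equal blend keeps correlated scores grouped (ridge
behavior) while still zeroing useless ones (lasso behavior) — and record
it in the fitted `mix_weights` object; it is configurable throughout.

## Harmonization policy

Weights are re-expressed per copy of the panel's alternative allele:
records whose effect allele is the panel's alt keep their sign, records
whose effect allele is the panel's ref are negated, and everything else —
variants absent from the panel, allele pairs that do not match, and
multi-allelic sites — is dropped and counted, never silently altered.
Palindromic A/T and C/G sites are dropped by default because strand cannot
be resolved without allele-frequency heuristics, which we deliberately do
not attempt; `keep_ambiguous = TRUE` retains them for panels known to be
strand-consistent. rsID-only records are positioned through a
user-supplied map or dropped. Duplicate variant identifiers in a scoring
file are a hard error: they usually indicate upstream file corruption, and
summing them silently would bias the score.

## Evaluation conventions

The best-single baseline is always *selected on the training split and
evaluated on the test split*, the same protocol as the combination, so the
fold-ratio $R^2_{\text{combined}} / R^2_{\text{best single}}$ compares two
honestly held-out quantities. `improvement_test()` aggregates fold-ratios
across traits with a one-sample t-test against 1 (the paired-on-$R^2$
variant is available via `paired = TRUE`). For clinical utility,
`category_free_nri()` uses strict inequalities for up/down classification
(ties count as neither and are reported), `incremental_auc()` uses the
rank/concordance AUC with ties at one half, and both use a 500-replicate
percentile bootstrap for confidence intervals — one bootstrap convention
throughout rather than mixing analytic and resampling intervals.
Quasi-separation in any logistic fit raises a diagnostic error instead of
returning an unbounded estimate.

## What the simulation engine emulates

`simulate_genotypes()` draws independent biallelic variants in
Hardy-Weinberg equilibrium with MAF uniform on (0.01, 0.5).
`simulate_effects()` draws per-score SNP effects for $M$ causal variants
from $\mathrm{MVN}(0, \Sigma)$ with $\Sigma_{ii} = h^2/M$ and
$\Sigma_{ii'} = r_g h^2 / M$ — $r_g = 0.8$ within the block of three
trait-specific scores and $0.4$ for every pair involving the three
cross-trait (pleiotropic) scores. The outcome's genetic value $g$ is a
$U(0,1)$-weighted combination of the component genetic scores and the
phenotype is $y = g + e$, $e \sim N(0, 1 - h^2)$.

Two numerical choices matter here. First, with finite $M$ and realized
genotypes the raw weighted combination does not have variance exactly
$h^2$, so $g$ is standardized and rescaled to variance exactly $h^2$ —
otherwise the stated noise distribution would not produce a unit-variance
phenotype; the test suite asserts $\operatorname{var}(g) = h^2$ to 1e-6.
Second, the combination weights are drawn once per replicate and returned,
so every replicate is fully reproducible from its seed.

What the generator does *not* emulate: linkage disequilibrium (variants
are independent), population structure, genotyping error, and
ascertainment. The training-size experiments operate on PRS-level
quantities, which do not depend on LD once per-SNP effects are estimated,
but absolute GWAS accuracy at a given sample size will be optimistic
relative to real data. Passing tests therefore demonstrate the
correctness and qualitative behavior of the combination machinery, not
real-cohort effect sizes.

## The training-size sweep

`sweep_training_sizes()` reproduces the training-size / heritability
experiment at desk scale. Each replicate allocates pairwise-disjoint GWAS,
training-pool and test sets; estimates each component score's per-SNP
effects by marginal regression on the GWAS set (the estimated slopes at
the causal variants are the score weights — no pruning is needed without
LD); fits the trait-specific mixture (3 scores) and the cross-trait
mixture (all 6) at each training size; and evaluates fold-ratios on the
fixed test set. The baseline is the best-performing *trait-specific*
single score, identified on the full training pool — one reference per
replicate, so the baseline does not vary with the mixing training size —
and evaluated on the test set. `improvement_slope()` then regresses the
mean fold-ratio on $\log_{10}(N_{\text{train}})$ per heritability level.

The shipped experiment uses $M = 200$ causal SNPs, a 5,000-sample GWAS,
training sizes $\{250, 1000, 4000\}$, 1,500 test samples and 20 replicates
per heritability level $h^2 \in \{0.1, 0.5\}$ — sizes chosen so the full
design runs on a laptop in under a minute while leaving the qualitative
conclusions (combination helps; more training data helps; low-heritability
traits gain most) clearly resolved against Monte-Carlo noise. The
reference design scales these up (e.g. $M = 1000$, 200 replicates, GWAS
cohorts in the hundreds of thousands); `sim_config()` exposes every size.

## Degenerate inputs and tie-breaking

* A single candidate score bypasses the penalized path (a one-column
  elastic net is ill-posed) and is fitted unpenalized; the combination is
  then a monotone rescaling of that score.
* If cross-validation selects the all-zero score model, the result is
  reported as non-informative rather than silently falling back to the
  best single score.
* The top-decile cut uses the evaluation sample's own 90th percentile;
  ties at the threshold stay in the remainder group.
* Scores with zero training-set variance, phenotype strata that would
  empty a split, and CV folds with a single class are all hard errors
  naming the offender.

## Known limitations

Mixing weights are trained in one cohort and are not externally
validated; genotype input is dosage-matrix based (a VCF must be exported
to dosages first); liability-scale conversion assumes the sample
prevalence approximates the population prevalence unless told otherwise;
and the simulation engine's independence assumptions make it a testbed
for the combination machinery rather than a forecast of real-data gains.
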