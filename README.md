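# mesrec

Association analysis between a mesenchymal-transition gene-expression
metagene and time to tumor recurrence in glioma cohorts.

## The problem

Glioblastoma patients who respond to initial therapy differ enormously in
how long the tumor stays away. A recurring observation in bulk expression
data is that a coordinately expressed set of epithelial–mesenchymal
transition (EMT) markers — collagens, SNAI2/Slug, FN1, POSTN and related
extracellular-matrix genes — varies continuously across tumors, as if
tumors pass through a mesenchymal transition to varying degrees. `mesrec`
implements the statistical machinery for asking whether *absence* of that
program accompanies exceptionally long time to recurrence:

- **Metagene scoring.** The signature's activity in a sample is the
  unweighted mean of the log2 normalized expression of its genes (the
  64-gene Slug-based EMT signature ships with the package as
  `emt_signature()`).
- **Rank-sum association.** Rank the `n` phenotyped samples by metagene
  score (rank 1 = lowest). For the `k` patients with exceptionally long
  recurrence (> 3 years by default), the statistic is the sum `R` of their
  ranks. Under the null, the subset is a uniform random `k`-subset of
  `{1..n}`, so `P(R_null ≤ R_obs)` is a finite combinatorial quantity. The
  package computes it two ways: an **exact integer dynamic program** that
  counts `k`-subsets of `{1..n}` with bounded sum (no floating point until
  the final division by `C(n,k)`), and a seeded Monte-Carlo permutation
  estimator (ten million draws by default, in compiled code).
- **Genome-wide scan.** The same rank sum for every single gene — the
  signature's claim to fame is that the *metagene* scores better than any
  individual gene, including its own components.
- **Survival models.** Kaplan–Meier curves with a two-sample log-rank test
  for the median split into metagene-high vs metagene-low, univariate Cox
  proportional-hazards regression on the metagene, and multivariate Cox
  with sum-to-zero (deviation) coded tumor subtype, reported as all four
  subtype-vs-overall-mean contrasts via the two-fit device.
- **Subtype imputation.** Ten-nearest-neighbour imputation of missing
  subtype labels on z-scored subtype signature genes.
- **Gene-level utilities.** Pearson correlation with t-distribution
  p-value, mutual-information gene ranking (equal-frequency binning,
  Miller–Madow corrected, bits), linear fold-change ranking between tumor
  grades, and hypergeometric gene-set enrichment.
- **Synthetic cohorts.** A single-latent-factor generator
  (`simulate_cohort()`) that emulates the data structure the analysis
  assumes — continuous mesenchymal activity, loaded signature genes,
  independent background genes, Weibull recurrence times whose log hazard
  rises with activity, non-responders with null recurrence entries,
  optional subtype centroids — and returns the ground truth for
  parameter-recovery testing. `default_gbm_like_params()` is sized to a
  TCGA-GBM-like cohort (545 samples, 99 expected responders, 12,042 genes).

## Worked example

```r
library(mesrec)

params <- default_gbm_like_params(seed = 7, n_background_genes = 2000L)
cohort <- simulate_cohort(params)
sig    <- emt_signature()

clin <- cohort$clinical
long <- select_long_recurrence(clin)              # recurrence > 1095 days
resp <- clin$sample_id[clin$responder]
scores <- compute_metagene(cohort$expression[, resp], sig)

rank_sum_test(scores, long, n_perm = 1e6, seed = 7)
#> <rank_sum_result> n = 109, k = 10
#>   member ranks: 1 + 6 + 7 + 9 + 11 + 12 + 13 + 16 + 20 + 38 = 133
#>   exact P(R <= 133) = 2.79625e-07
#>   Monte-Carlo P = 0 (SE 0, 1e+06 draws, seed 7)

surv  <- as_survival_dataset(clin)
split <- median_split(compute_metagene(cohort$expression, sig))
km_logrank(surv, split[surv$sample_id])
#> <km_logrank> groups low vs high: chi-squared = 58.3 (1 df), P = 2.245e-14

cox_univariate(surv, scores[surv$sample_id])
#> <cox_fit> n = 109, events = 109
#>       term coef    se                  hr_ci        p
#>  covariate  3.1 0.341 22.177 (11.375-43.235) 9.17e-20
#> Likelihood ratio test = 95.9, df = 1, P = 1.212e-22
```

Reading the numbers: of 109 responders in this simulated cohort, the ten
whose tumors stayed away longer than three years occupy ranks
1, 6, 7, … 38 of the metagene ranking — they are almost exactly the
lowest-signature tumors. Ten ranks drawn at random would sum to 550 on
average; a sum of 133 or less has exact null probability 2.8×10⁻⁷ (the
Monte-Carlo estimate at 10⁶ draws sees no hits, which is why the exact
null matters at these magnitudes). The log-rank and Cox fits show the same
association as survival models. A genome-wide scan
(`genome_wide_scan()`) confirms the synergy property: no single gene, in
or out of the signature, scores a lower rank sum than the metagene.

The same analysis runs end to end from a config via `run_pipeline()`
(TSV artifacts, KM plot, deterministic manifest), or from a shell through
the thin wrapper `inst/scripts/mesrec.R` (`simulate` and `run`
subcommands).

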