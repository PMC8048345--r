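# trajsurv

Sparse Cox gene selection and alignment-kernel clustering of
longitudinal expression trajectories.

## The problem

Prospective clinical transcriptomics studies follow patients with
repeated blood draws on an irregular schedule and record a time-to-event
outcome — here, hospital length of stay, where the event is *discharge*
(a good outcome: "high risk" means earlier discharge). Two questions
drive the analysis:

1. Which of tens of thousands of genes, measured in the first days,
   predict the time until discharge?
2. Do patients with similar expression *trajectories* over the follow-up
   also share similar discharge times?

trajsurv implements a complete, tested pipeline for both, for R users
working with survival + expression data at `p >> n`.

## Methods at the core

* **Elastic-net Cox regression**, fitted by cyclical coordinate descent:
  maximise the penalized partial log-likelihood
  `l(beta) - lambda * (alpha * ||beta||_1 + (1 - alpha) * ||beta||_2^2)`
  with Breslow ties, a glmnet-style lambda path, and cross-validated
  penalty choice (Verweij–van Houwelingen deviance). Exact KKT
  conditions are verified at every solution.
* **Stability selection**: genes with nonzero coefficients in *all* `n`
  leave-one-out refits form a per-day stable set; the union across
  selection days (default days 0, 1, 4) is the gene signature.
* **Mixed imputation**: a reduced time grid (days with < 50% missing),
  LOCF/NOCB carrying within a 2-day window, linear interpolation as
  fallback, and complete-case splits at horizon days 7 and 28 — no
  extrapolation past discharge, full per-cell provenance.
* **Triangular Global Alignment Kernel + PAM**: the GAK sums local
  Gaussian kernels over all monotone alignments of two multivariate
  series (log-space dynamic programming); the normalised form
  `d = 1 - exp(logk_ij - (logk_ii + logk_jj)/2)` is a `[0, 1]`
  dissimilarity. Partition-around-medoids clusters the cross-distance
  matrix; the number of clusters is chosen by the smallest log-rank
  p-value across the clusters' Kaplan–Meier curves.
* **A synthetic cohort generator** with planted prognostic genes,
  planted trajectory clusters, irregular sampling, draw-level
  missingness, loss of follow-up after discharge and administrative
  censoring — every stage of the pipeline is testable without any
  external download.

## Worked example

```r
library(trajsurv)

cfg <- cohort_config(n_patients = 100, n_genes = 120, n_active_genes = 6,
                     n_clusters = 3, seed = 42)
sim <- simulate_cohort(cfg)

# day-0 snapshot -> cross-validated elastic-net Cox fit
X  <- day_snapshot(sim$expression, 0)
sv <- sim$survival[match(rownames(X), sim$survival$patient_id), ]
cv <- cv_coxnet(X, sv, alpha = 0.8, n_folds = 5, seed = 1)
cv$fit
#> elastic-net Cox fit: alpha = 0.8, lambda = 0.1056, 16 nonzero of 120 coefficients

# the 16 selected genes include all 6 planted prognostic genes; a
# median split of the linear predictor separates discharge strongly
risk_stratify(cv$fit, X, sv)$test
#> log-rank chi-square = 73.28 on 1 df, p = 1.127e-17

# longitudinal phase: reduced grid, imputation, horizon split, clustering
grid <- select_time_points(sim$expression, 0.5, surv = sim$survival)
grid$selected_days
#> [1]  0  1  4  7 14 21 28
sig <- names(cv$fit$beta)[cv$fit$beta != 0]
ser <- impute_mixed(sim$expression[sim$expression$gene_id %in% sig, ], grid)
cc  <- split_complete_cases(ser, 7)
cc
#> series set: 53 patients x 4 days (0,1,4,7) x 16 genes, 0 missing cells
select_k(cc, sim$survival, k_range = 2:4, seed = 1)
#> cluster-number selection by log-rank survival separation
#>  k admissible   logrank_p     wald_p min_size
#>  2       TRUE 0.006217058 0.02654243       16
#>  3       TRUE 0.013942942 0.05743094        9
#>  4       TRUE 0.037182790 0.90624574        6
#> selected k = 2
```

Reading the output: the day-0 model keeps 16 of 120 genes at the
cross-validated penalty; splitting patients at the median risk score
separates their discharge curves (log-rank p ≈ 1e-17, with earlier
discharge in the high-score half). The 53 patients still hospitalised
past day 7 have complete imputed series on the grid {0, 1, 4, 7}; PAM
on GAK distances with the smallest log-rank p-value picks two
trajectory strata whose discharge curves differ (p ≈ 0.006).

`run_pipeline()` chains all stages (shared alpha choice, per-day
leave-one-out stability selection, union signature, imputation,
clustering per horizon) under one seed, and `write_report_bundle()`
writes a deterministic set of CSV/JSON artifacts.

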