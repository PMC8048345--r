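---
title: "Coupling sparse Cox selection with alignment-kernel clustering of expression trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coupling sparse Cox selection with alignment-kernel clustering of expression trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

trajsurv analyses cohorts in which each patient contributes an irregular
short multivariate time series of gene expression and a time-to-event
outcome — the motivating setting is hospital length of stay after severe
trauma, where the "event" is discharge, a *good* outcome, so high risk
means *earlier* discharge throughout. The pipeline has two phases:

1. **Static phase.** Per-day expression snapshots feed elastic-net Cox
   models; a stability criterion (leave-one-out intersection of model
   supports) distils a small gene signature.
2. **Longitudinal phase.** The signature genes' trajectories are
   completed by a mixed carry/interpolation imputation on a reduced time
   grid, compared with a triangular Global Alignment Kernel (GAK)
   distance, clustered with partition-around-medoids (PAM), and the
   patient strata are validated by Kaplan–Meier curves and log-rank
   tests.

# Survival core

The hazard for patient $i$ with covariates $x_i$ is
$h(t; x_i) = h_0(t)\exp(x_i^\top\beta)$. Coefficients maximise the
partial log-likelihood
$\ell(\beta)=\sum_i \delta_i\{x_i^\top\beta - \log\sum_{j\in R(t_i)}
e^{x_j^\top\beta}\}$ with risk sets $R(t)=\{j: t_j\ge t\}$. Tied event
times use the Breslow convention everywhere — the baseline-hazard
increments are then $\hat h_0(t_i)= d_i/\sum_{j\in R(t_i)}
e^{x_j^\top\beta}$, which is also what `breslow_baseline()` returns.
The proportional-hazards check (`schoenfeld_ph_test()`) is the
Grambsch–Therneau score test for a time-varying coefficient
$\beta(t)=\beta+\theta\,g(t)$ with the identity transform
$g(t)=t$ centred over events; it is the simplest variant and matches
`survival::cox.zph(transform = "identity")`.

Harrell's c-index uses a strict comparability convention: pair $(i,j)$
is comparable only when $\delta_i=1$ and $t_i<t_j$; pairs tied in time
are non-comparable, tied scores count 1/2. Day-resolution outcomes
produce many ties, so reported c-indexes are conservative relative to
implementations that score event/censored ties.

# Elastic-net Cox solver

The solver minimises
$-\ell(\beta)/n + \lambda\{\alpha\lVert\beta\rVert_1 +
(1-\alpha)\lVert\beta\rVert_2^2\}$
by iteratively reweighted least squares with cyclical coordinate
descent, the standard approach of the glmnet family. Numerical choices:

* **Scaling.** The likelihood term is scaled by $1/n$, so $\lambda$ is
  comparable across cohort sizes; genes are standardized internally to
  unit (population) variance and coefficients are returned on the
  original scale. Note the ridge term is $(1-\alpha)\lVert\beta\rVert_2^2$,
  not $(1-\alpha)/2\,\lVert\beta\rVert_2^2$; when cross-checking against
  glmnet use $\lambda_g=\lambda(2-\alpha)$, $\alpha_g=\alpha/(2-\alpha)$.
* **Path.** $\lambda_{\max}$ is the smallest penalty with an all-zero
  solution, $\max_j |\nabla_j(-\ell/n)|/\alpha$ at $\beta=0$; a
  30-point geometric path descends to `lambda_min_ratio` (default 0.05,
  suited to $p\gg n$) with warm starts, sequential strong-rule
  screening, and a saturation stop once the deviance ratio exceeds
  0.99 (later fits carry the last solution).
* **Convergence.** The sweep-level tolerance (default `1e-7`) is on the
  weighted squared coefficient change, glmnet's `thresh` scale. On top
  of it the solver verifies the exact-gradient KKT conditions of the
  true objective — $|\nabla_j| \le \lambda\alpha$ for zero
  coefficients, $\nabla_j + \lambda\alpha\,\mathrm{sign}(\beta_j) +
  2\lambda(1-\alpha)\beta_j \approx 0$ for active ones — and keeps
  iterating until they hold (`kkt_tol`, `1e-6` on paths, `1e-8` for
  single fits). `coxnet_kkt()` exposes the residuals for auditing.
* **Degenerate input.** Zero-variance genes are excluded with a warning
  and reported in the fit's standardization record.

Cross-validation (`cv_coxnet()`) scores each $\lambda$ by the
Verweij–van Houwelingen partial-likelihood deviance
$-2\{\ell_{\text{full}}(\hat\beta_{-k}) -
\ell_{\text{train}}(\hat\beta_{-k})\}$, with folds stratified by event
status and re-randomized (bounded retries) if a training fold has no
events. The default selection rule is the deviance minimum; the
conservative one-standard-error rule (`rule = "1se"`) is available and
is the better choice when the goal is to suppress noise genes rather
than maximise predictive likelihood — on pure-noise data the minimum
rule routinely keeps a handful of spurious genes, while the 1se rule
returns (near-)empty models.

# Stability selection and the union signature

`loocv_intersection()` refits the cross-validated model on each of the
$n$ leave-one-out training sets and keeps the genes with nonzero
coefficients in *every* completed fit. Inside these $n$ refits the
penalty is re-cross-validated with 5 folds (10-fold doubles the cost of
the $n$ refits without changing the recovered sets appreciably). The
per-day stable sets are merged by `build_union_signature()`, which
records per-gene provenance (the days that selected it).

A power limit worth knowing: when $m$ genes contribute comparable
independent signal, each gene's effective information is roughly
$z \approx \sqrt{\text{events}/m}$, while the largest spurious
association among $p$ inactive genes scales as $\sqrt{2\log p}$. With
$m = 10$, $p \approx 500$ and one to two hundred events the two are of
the same order, so no support-selection method can recover such a
signature near-perfectly; stability selection should be read as
high-precision, moderate-recall. The union across selection days
recovers more of the signal than any single day.

`select_alpha()` picks the elastic-net mixing by held-out concordance
on one shared 70/30 patient split (ties prefer the larger, sparser
$\alpha$; with several selection days the mean c-index across days
decides, mirroring a single shared choice). `risk_stratify()` splits a
test cohort at the median linear predictor into high/low risk halves
differing by at most one patient and compares them by log-rank.

# Mixed imputation on a reduced grid

`select_time_points()` keeps the days whose missingness is *strictly*
below the threshold (default 50%); the denominator counts patients
still under follow-up at that day when a survival table is supplied
(the default reading), or all patients otherwise — a documented switch,
since either convention is defensible.

`impute_mixed()` resolves each required (patient, day, gene) cell in
order of preference: observed value; nearest draw within the 2-day
carry window (past → LOCF, future → NOCB, nearest wins, equidistant
ties prefer the past — carrying forward is listed first in the
procedure and favours information that existed at the required day);
linear interpolation between the closest bracketing draws. Carrying
moves whole per-day draw vectors because missingness is draw-level (all
genes of one blood sample are present or absent together). There is no
extrapolation past a patient's last draw: trailing cells stay missing
and are resolved by `split_complete_cases()`, which keeps the patients
fully resolvable up to a horizon day (7 and 28 by default) — the
complete-case split is how loss of follow-up after discharge is
handled, rather than guessing post-discharge expression. Every cell
carries a provenance tag (`observed`, `carried_forward`,
`carried_backward`, `interpolated`, `missing`), so window compliance is
auditable. Expression is assumed log-scale on input; base-2 is the
package convention when transforming upstream.

# GAK distance and PAM clustering

For two patients' series the local cost matrix is
$LCM_{ij}(q,r) = \lVert x_i^{T_q} - x_j^{T_r}\rVert$ across the shared
gene dimension. The Global Alignment Kernel sums, over all monotone
alignments, products of the normalised Gaussian local kernel
$\exp\{-\varphi_\sigma(a,b)\}$ with
$\varphi_\sigma(a,b) = \lVert a-b\rVert^2/2\sigma^2 +
\log(2 - e^{-\lVert a-b\rVert^2/2\sigma^2})$,
optionally multiplied by a triangular integer window of a given order
(order 0 = unconstrained, the default here: with only seven grid points
a band constraint is unnecessary). The dynamic program
$M(q,r)=\kappa(q,r)\{M(q-1,r)+M(q,r-1)+M(q-1,r-1)\}$ runs in log space
because kernel values decay exponentially with series length. The
normalised dissimilarity is
$d(i,j) = 1 - \exp\{\log k(i,j) - \tfrac12(\log k(i,i)+\log k(j,j))\}
\in [0,1]$; it is symmetric with $d(x,x)=0$ but is *not* a metric (no
triangle inequality), which PAM on a precomputed matrix does not
require. The bandwidth default follows the median heuristic
$\sigma = c\cdot\mathrm{med}\lVert x^{T_q}_i - x^{T_r}_j\rVert\cdot
\sqrt{|T|}$ over a seeded subsample, $c=1$.

`pam_cluster()` is Lloyd-style alternation on the precomputed matrix
(assign to nearest medoid, move each medoid to the member minimising
the within-cluster distance sum), with seeded random initialization,
10 restarts keeping the best objective (single-start alternation is
prone to local optima), and re-seeding of emptied medoids. The
objective is non-increasing within a run. `select_k()` clusters for
each candidate $k$, discards solutions with a cluster smaller than
`min_cluster_size` (default 2; raise it on larger cohorts — tiny
chance clusters produce spuriously extreme log-rank p-values), and
picks the $k$ with the smallest log-rank p-value across cluster
survival curves. A Wald-style companion p-value from an unpenalized
Cox fit on cluster indicators is reported alongside. The minimum-p
protocol is the study's own selection rule; note it is a noisy
selector — when all candidate partitions separate survival strongly,
the ranking among tiny p-values is close to arbitrary, so it sometimes
prefers a split of a true cluster (it essentially never merges
well-separated ones).

Complete-case horizon splits interact with a survival-linked cluster
structure: patients in the fast-discharge stratum rarely survive to the
later horizon, so the day-28 complete-case set over-represents the
slow-discharge clusters and its recovered partition can look much
weaker than the day-7 one. This informative attrition is a property of
the complete-case strategy itself, not of the clustering.

# The synthetic cohort generator

`simulate_cohort()` emulates the design the analysis assumes:

* the irregular 22-day blood-draw schedule with day-dependent draw-level
  missingness (core days 0, 1, 4, 7, 14, 21, 28 well sampled at 30%
  missing, in-between days sparse at 70%);
* log2-scale expression around per-cluster exponential-decay
  injury-response curves $b_g + a_{gc}e^{-r_c t}$ for active genes and
  flat baselines for inactive ones, with persistent per-patient gene
  offsets (`patient_sd`, default 0.7 log2 units) that make a patient's
  repeated draws correlate, plus per-draw noise (`noise_sd`, 0.5);
* discharge times from a Weibull proportional-hazards model (shape 1.3,
  scale 18 days; closed-form inverse-CDF sampling) whose linear
  predictor applies the planted coefficients to the *realized* day-0
  active-gene values, centred at their cross-cluster expectation; event
  days are rounded up to whole days (a day-resolution length of stay,
  with the resulting ties), follow-up is truncated at the
  administrative censoring day and expression records after discharge
  are removed;
* `severity_link = TRUE` switches the planted clusters to an ordered
  severity gradient (response amplitudes aligned with the hazard signs,
  scaled by equally spaced cluster scores), guaranteeing pairwise
  survival separation between clusters; the default random response
  directions differentiate clusters in trajectory space but link them
  to survival only incidentally.

The default Weibull and amplitude scales were chosen so the simulated
length-of-stay distribution has a realistic shape — median stay around
ten days, a substantial fraction of the cohort still hospitalised past
day 7, and 30–40% administratively censored at day 28 — rather than
collapsing into a discharged-immediately/never-discharged dichotomy.
All randomness derives from one root seed split into documented stage
streams (cluster structure, expression, event times, missingness), so
equal seeds give byte-identical cohorts.

What the generator does **not** emulate: microarray platform artefacts
(probe effects, batch, normalization), competing risks (death before
discharge is treated as right-censoring only — the study outcome did
not distinguish them), informative missingness, or gene–gene
correlation beyond the planted cluster structure. Passing tests on this
generator therefore demonstrate the machinery's correctness and the
statistical behaviour of the procedures under the assumed model, not
robustness to those real-data features.

# Orchestration and problem sizes

`run_pipeline()` chains the two phases under one `pipeline_config()`
and one root seed (split, CV folds, leave-one-out refits, bandwidth
subsample and PAM initialization use derived stage streams), and
`write_report_bundle()` writes deterministic text artifacts (selection
report, signature with provenance, imputed series with cell provenance,
partitions, k-selection tables, run manifest with a config hash) —
rerunning with the same inputs reproduces the bundle byte for byte.
Patients lacking a draw on a selection day are excluded from that day's
model rather than imputed; imputation is reserved for the longitudinal
phase, and only signature genes enter it.

The test suite exercises cohorts up to $n=150$ patients and $p=500$
genes with ten-seed replications for the recovery properties, and
smaller fixtures (down to $n\le 8$) where exhaustive oracles — alignment
enumeration for the GAK kernel, pair enumeration for the c-index,
medoid-pair search for PAM — are feasible. These sizes were chosen so
every property is checked by an independent oracle or a seeded
replication at desk scale.
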