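---
title: "Methods: normative connectivity anomalies and recovery-trajectory phenotyping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: normative connectivity anomalies and recovery-trajectory phenotyping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strokeconn)
```

# The analysis in one paragraph

`strokeconn` implements a connectome-based phenotyping workflow for acute
stroke patients treated with repetitive transcranial magnetic stimulation
(rTMS). It has three scientific stages. First, a *normative model* of
functional connectivity is fitted from a healthy reference cohort: each
subject's region-by-region correlation matrix is projected to the tangent
space of the SPD manifold at the cohort's Fréchet mean, giving every region
pair a normative mean and standard deviation; a patient's pairs falling more
than three normative SDs away are labelled hypo- or hyperconnected, and the
highest-variance third of pairs is excluded up front. Second, each patient's
recovery trajectory — scores on the NIHSS, FMA, BI and WMFT stroke scales at
admission and 1, 30 and 90 days after treatment — is clustered per scale by
agglomerative hierarchical clustering, with the number of clusters chosen by
the silhouette criterion. Third, a nonparametric statistical battery compares
timepoints (Friedman with Kendall's W and Dunn post hoc) and compares
connectivity features between the recovered phenotypes (Kruskal–Wallis with
Dunn/Bonferroni, gated t/Wilcoxon two-group tests, chi-square/Fisher for
categorical tables).

Because no patient-level data are distributed with studies of this kind, the
package ships a fully seeded synthetic-cohort generator so that every stage
is exercised and tested end to end without any download.

# Normative tangent-space model

## Why tangent space

Correlation matrices live on the cone of symmetric positive-definite (SPD)
matrices, where entry-wise statistics misbehave (averages of correlation
matrices are biased toward singularity; per-pair SDs ignore the coupling
between pairs). The affine-invariant Riemannian metric fixes this: matrices
are mapped through

$$T = \log\!\left(M^{-1/2}\, C\, M^{-1/2}\right),$$

where $M$ is the Fréchet (Karcher) mean of the reference cohort and the log
is the symmetric matrix logarithm computed by eigendecomposition. In this
linearized space per-pair means $\mu_{ij}$ and SDs $\sigma_{ij}$ are
well-defined, and a patient's z-scores
$z_{ij} = (t_{ij} - \mu_{ij})/\sigma_{ij}$ quantify how far each connection
sits outside the healthy range. At the reference itself the image is the zero
matrix, and for a $2\times 2$ correlation with the identity reference the
off-diagonal image is $\operatorname{atanh}(r)$ — the familiar Fisher
transform emerges as a special case.

The metric is a deliberate choice: the tangent-space construction is named by
the field but admits several metrics, and the affine-invariant one is the
standard for functional-connectivity normative models. The per-pair ranges
are computed on tangent values rather than raw correlations for the same
reason (the raw-correlation alternative is exposed nowhere; it would couple
the threshold to the local curvature of the correlation manifold).

## Estimation pipeline and parameters

* `estimate_connectivity(ts, lambda = 0.05)` — Pearson correlation with
  shrinkage $(1-\lambda)C + \lambda I$. Shrinkage guarantees positive
  definiteness when scans are short relative to the region count (motivating
  acquisitions: 128 volumes against 45 regions). $\lambda = 0.05$ perturbs
  strong correlations by at most 0.05 while bounding the smallest eigenvalue
  away from zero; it is configurable per run.
* `frechet_mean(mats, tol = 1e-9, max_iter = 100)` — fixed-point iteration
  initialized at the log-Euclidean mean. The tolerance is on the Frobenius
  norm of the mean tangent; the tight default costs a handful of extra
  iterations and keeps the mean accurate to ~1e-8, which is the level at
  which the two-matrix case reproduces the closed-form geodesic midpoint.
* `fit_normative(cohort, sigma_threshold = 3, mask_fraction = 1/3)` — per-pair
  tangent mean/SD with denominator $n-1$; the $\lceil P/3 \rceil$ pairs with
  the largest normative SD (out of $P = R(R-1)/2$) are masked, ties broken by
  row-major pair order so the mask is reproducible. Pairs that vary most
  across healthy subjects are those most prone to false discovery in
  patients. At $R = 45$: $P = 990$ pairs, 330 masked.
* `score_anomalies(patient, model)` — labels `hyper` for $z > 3$ strictly,
  `hypo` for $z < -3$ strictly, `normal` otherwise. The boundary is
  inclusive: a pair exactly at three SDs is within range. Under a Gaussian
  null the expected flag rate is $2\Phi(-3) \approx 0.27\%$ of unmasked
  pairs, and the package's null-calibration test checks the empirical rate
  stays between 0.05% and 2%.
* `count_anomalies(am, lesion_side)` — regions on the lesion hemisphere are
  ipsilesional, the rest contralesional (a midline brainstem node is reported
  as `midline`). Each anomalous pair increments both endpoint regions, and
  totals are reported both as incident-pair counts and as parcel flags
  (regions with at least one anomaly): region-level summaries in the
  literature use both conventions interchangeably, so both are produced and
  incident counts are the default in reports.

# Recovery-trajectory clustering

Subjects are represented by their raw 4-vector of scores
(baseline, day 1, day 30, day 90) for one scale. The vectors are
*unstandardized*: all four entries share the scale's units, so standardizing
would only re-weight timepoints arbitrarily. Distances are Euclidean, the
tree is built by agglomerative clustering (Ward linkage by default — the
natural companion of Euclidean distances; `average` and `complete` are
selectable), and the tree is cut at every $K$ in `2:min(10, n - 1)`. The mean
silhouette
$s(i) = (b_i - a_i)/\max(a_i, b_i)$ (0 for singletons) selects $K$; ties go
to the smallest $K$. The upper bound of 10 reflects the intended cohort
sizes: with a couple dozen patients, solutions beyond ~10 clusters degenerate
into singletons, which is exactly the failure mode that motivates clustering
each scale separately — pooling heterogeneous scales into one feature matrix
produces >14 near-singleton clusters on small cohorts, so `cluster_all_scales()`
always fits one solution per scale and no joint mode is offered.

Everything in this stage is deterministic: there is no random initialization,
cluster ids are renumbered in order of first appearance, and rerunning on the
same table is bit-identical.

# Statistical battery

* `friedman_w_test` — tie-corrected Friedman chi-square (delegated to
  `stats::friedman.test`) with $k-1$ df and Kendall's
  $W = \chi^2 / (n(k-1))$, which is 1 under perfect concordance and invariant
  to monotone transforms. The asymptotic p-value is used throughout; at very
  small $n$ the chi-square approximation is accurate in the moderate-p range
  but anti-conservative in the extreme tail, which the tests document by
  comparing against an exact within-row permutation enumeration at
  $n=4, k=3$.
* `dunn_posthoc_friedman` — pairwise z-tests on timepoint mean ranks with
  standard error $\sqrt{k(k+1)/(6n)}$ and Bonferroni over all
  $k(k-1)/2$ pairs.
* `compare_clusters_numeric` — tie-corrected Kruskal–Wallis omnibus; Dunn
  pairwise z-tests (tie-corrected pooled variance, Bonferroni) run only when
  the omnibus p is at or below `alpha`. This is the workhorse for per-region
  anomaly counts and structural ratings across phenotypes; no omnibus test is
  canonical for such data, and Kruskal–Wallis keeps the package's
  nonparametric stance on small samples. Per-region comparisons are reported
  with both raw and Bonferroni-adjusted p-values rather than choosing one.
* `compare_two_groups_continuous` — the demographic-table rule: Shapiro–Wilk
  on both groups plus an F-test of variances; all gates passing at
  `alpha = 0.05` selects the unpaired t-test, anything else (including
  degenerate inputs where the gates cannot run) selects the Wilcoxon rank-sum
  test. Every decision is returned in a `gating_trace` so reports are
  auditable.
* `categorical_association` — Fisher's exact test when any expected cell
  count is below 5, otherwise chi-square with Yates continuity correction
  (2x2 only; larger tables use Fisher when feasible).

# The synthetic-data generator

The generator defines the study conditions under which the pipeline is
validated:

* **Normative cohort** — subject covariances are Wishart draws
  $\Sigma_s \sim W(\kappa, \Sigma_0/\kappa)$ around a seeded unit-diagonal
  base correlation matrix $\Sigma_0$ (low-rank loading construction,
  optionally with community blocks). The draw is mean-preserving and
  $\kappa$ (default 100) controls inter-subject dispersion; this jitter is
  what makes the highest-variance mask non-degenerate. Each subject then
  yields $T$ iid Gaussian samples, renormalized to unit variance per region.
  Temporal autocorrelation is deliberately omitted — the analysis consumes
  only spatial covariance.
* **Patients** — the base matrix is perturbed in its own tangent space by
  $\pm m \cdot \sigma_{ij}$ at planted pairs and mapped back with the
  exponential, which preserves positive definiteness by construction. When a
  fitted model supplies $\sigma_{ij}$ it is used directly; otherwise the
  analytic default $\sqrt{1/\kappa + 1/T}$ (jitter plus sampling
  variability) stands in. Recovery experiments plant into pairs the fitted
  model keeps unmasked: the mask is known before any patient is seen, and
  planting into masked pairs would measure the mask, not the detector.
* **Trajectories** — cluster mean 4-vectors plus iid Gaussian noise, rounded
  to integers (clinical scales are integer-valued) and clipped to the scale
  range. The default specification emulates a 22-patient acute cohort with
  6/2/5/2 planted phenotypes on NIHSS/FMA/BI/WMFT and baselines near the
  cohort means (NIHSS ~11, FMA ~16, BI ~9, WMFT ~12).
* **Structural ratings** — 3-point integrity and lesion-proximity scores per
  tract class, drawn from cluster-conditional categorical distributions with
  an `association_strength` dial from 0 (no association) to 1 (deterministic
  within cluster).

All generators draw from a private, restored RNG stream; operations derive
distinct default seeds from the specification's base seed so cohorts,
patients and trajectories are independent yet individually reproducible.

What passing tests on these cohorts shows — and does not show: the synthetic
data are Gaussian, stationary, artifact-free and perfectly labelled, so the
tests validate the estimators, the geometry, the calibration of the 3-sigma
rule under its own assumptions and the determinism of the pipeline. They do
not validate robustness to head motion, physiological noise, temporal
autocorrelation, registration error or rater disagreement in structural
scores, all of which are upstream of this package's inputs.

# Numerical and design choices

* **FMA bounds.** Published descriptions of the scale are inconsistent (a
  155-item, 3-point-per-item battery against the conventional total of 226),
  and severe-cohort baselines near 16 are compatible with motor subscales of
  several ranges. The default is `max_score = 226` and the bound is a
  constructor argument (`stroke_scales(fma_max = ...)`) rather than a guess.
* **Session duration.** Per-train active time is
  `pulses_per_train / frequency` (for iTBS, bursts-per-train over the burst
  rate), the inter-train interval is counted after *every* train including
  the last, and minutes are floored. This is the one convention that
  reproduces all three published durations (3, 18, 20 min) simultaneously.
* **Quantiles.** Median/IQR summaries use type-7 (linear interpolation)
  quantiles, R's default, since no quantile rule is canonical in clinical
  tables.
* **Missing timepoints.** Subjects lacking any of the four timepoints are
  flagged and excluded from clustering for that scale; no imputation is
  attempted anywhere.
* **Convergence and degeneracy.** `frechet_mean` errors with its last
  residual if 100 iterations do not converge; `fit_normative` rejects cohorts
  with zero tangent variance on an unmasked pair; `cluster_trajectories`
  rejects all-identical inputs; `silhouette_score` is undefined (an error)
  for a single cluster and 0 by convention for all-singleton partitions.
* **Problem sizes in the test-suite.** The heavy validation runs use
  reference cohorts of 200 subjects at 400 volumes with 10–20 regions for
  anomaly calibration and recovery (20 seeds), 100 seeds of 30-subject
  trajectory cohorts for cluster recovery, and 2000 null replicates for
  type-I calibration — sizes chosen so the full suite completes in a couple
  of minutes while keeping Monte-Carlo error well inside the asserted
  margins.

# Limitations

The package starts from region time series and already-scored structural
ratings; image acquisition, registration, parcellation, nuisance regression
and tractography are out of scope. The normative model assumes the reference
and patient scans share region definitions and comparable acquisition length;
the 45-region default label set is a synthetic stand-in, and real analyses
should supply their own parcel list. Silhouette-selected K on two dozen
subjects is a coarse instrument: the cluster-recovery guarantees quoted above
hold at 8-to-1 separation-to-noise and will degrade gracefully (correct K but
imperfect ARI, then merged clusters) as separation shrinks.
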