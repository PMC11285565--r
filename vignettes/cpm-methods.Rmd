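---
title: "Connectome-based predictive modeling: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Connectome-based predictive modeling: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpmr)
```

## The model

Connectome-based predictive modeling (CPM) predicts a behavioural score
from a functional connectome — the node-by-node matrix of Fisher
z-transformed Pearson correlations between regional fMRI time series.
The procedure, per cross-validation fold:

1. **Edge selection.** Within the training subjects, every edge's
   association with the score is measured by the *partial* Pearson
   correlation controlling for nuisance covariates (head motion, age and
   their interaction by default): both edge weight and score are
   residualized on the covariates by least squares and the residuals
   correlated. Significance uses the t-transform of the partial
   correlation with `df = n - 2 - c` (`c` covariates); edges with
   two-sided `p < alpha` (default 0.01) enter a positive or a negative
   set by the sign of the correlation.
2. **Summed connectivity.** Each subject's selected edges collapse to one
   scalar: the positive-set sum minus the negative-set sum ("combined"
   mode, the default; pure positive or negative sums are available for
   sensitivity analyses).
3. **Linear model.** The score is regressed on summed connectivity by
   ordinary least squares within the training folds, and the fitted line
   predicts the held-out fold.

A single run uses k-fold cross-validation (k = 5), so every subject is
predicted exactly once, out-of-fold. Because the fold partition is
random, the whole run is repeated over many iterations (1,000 at full
scale) and the ensemble is represented by its *median-performing*
iteration, ranked by the Spearman correlation between out-of-fold
predictions and observed scores. Performance is reported as Spearman's
rho and RMSE.

### Covariate handling

The covariates act through the selection step only: selection is by
partial correlation, while the fold-level prediction equation regresses
the score on summed connectivity alone. This is the convention in the
CPM covariate literature, where covariates are controlled when choosing
edges but the predictive model stays univariate. The alternative —
entering the covariates into the fold-level regression as well — is
available via `covariates_in_model = TRUE`; it changes the prediction
surface, not the selection.

### Significance

Model significance is permutation-based: the score vector is shuffled
relative to the connectomes and covariates (keeping the
covariate-connectome pairing intact, so the confound structure of the
null is preserved), the full procedure re-runs, and

\[ p = \frac{\#\{\rho_{null} \ge \rho_{median}\}}{n_{perm}} . \]

A raw 0 is displayed as `< 1/n_perm` but kept as 0 in machine output.
Across a grid of models (e.g. 7 scans x 3 scores per subject group), raw
p-values are Benjamini–Hochberg adjusted within each group's family.
Female-vs-male iteration performance is compared with two-sided Wilcoxon
rank-sum tests.

## Consensus edges and network summaries

An edge is a *consensus* ("significant") edge for a sign when it is
selected with that sign in at least 2 of the 5 folds in at least 40% of
the iterations. Both thresholds are parameters (`min_folds`,
`iteration_frac`); for non-default k the fold minimum generalises to
`ceiling(0.4 k)`. Two choices here were genuinely open:

* **The 40% bar is inclusive** (`>=` 400 of 1,000). The convention is
  not dictated by the rule's usual statement; we use `>=` and document
  it.
* **Both-sign conflicts.** An edge can in principle qualify with both
  signs. It is assigned the sign with the larger qualifying count; an
  exact tie drops the edge and records it in `tied_edges`. This keeps
  the per-sign consensus matrices disjoint.

Consensus edges are summarised between networks as counts normalized by
the number of possible edges between each network pair (`|A||B|` off the
diagonal, `|A|(|A|-1)/2` on it), and compared between groups by cellwise
subtraction. Within a network, each edge's signed selection total over
all folds and iterations (bounded by ±k·iterations, i.e. ±5,000 at full
scale) forms a heatmap, and each node's row sum over the symmetric
within-network matrix, divided by 2, gives the summed vector (SV). The
halving of a symmetric row sum is applied exactly as conventionally
stated for this quantity, even though it is an unusual normalization;
`halve = FALSE` gives the unhalved variant for sensitivity checks.

## Association ratio

The segregation metric for a network \(S\) in a weighted connectome
\(W\):

\[ AR(S) = \frac{\sum_{i<j,\; i,j \in S} w_{ij}}
                {\sum_{i<j,\; i,j \in S} w_{ij} +
                 \sum_{i<j,\; |\{i,j\}\cap S|=1} w_{ij}} \]

— the within-network weight as a fraction of all weight incident to the
network, each unordered edge counted once. For non-negative weights it
lies in [0, 1], increases with added within-network weight, decreases
with added boundary weight, and is invariant to global rescaling.
Design choices:

* **Denominator.** "Normalized by" suggests a superset denominator, so
  the default includes the within-network edges themselves; the strict
  within/boundary odds is available via `denominator = "boundary"`.
* **Raw signed weights.** Fisher-z weights enter unthresholded and
  signed; a near-zero denominator (|d| < 1e-12) makes the ratio
  undefined rather than exploding.
* **Group comparison.** Pooled-variance (Student) two-sample t-tests by
  default — the plain reading of "two-sample t-test" — with Welch
  available (`var_equal = FALSE`). BH correction is applied within each
  network across the scans tested (the 7-per-network family reading);
  `family = "all"` pools all cells instead.

## The synthetic cohort generator

`simulate_cohort()` provides ground truth for every stage. Per subject,
a standardized latent memory propensity \(z \sim N(0,1)\) is drawn;
observed scores are monotone discretizations of \(z\) plus independent
noise through a logistic squash onto their legal integer ranges (0–10
face-name recall, 0–75 verbal-learning sum, 0–15 immediate recall), so
rank relationships with \(z\) are preserved while bounds hold for any
input. Edge weights are generated directly on the Fisher-z scale:

```
w(e) = baseline(e) + beta(e) z [planted edges of the subject's sex]
       + gamma_m ffd_std + gamma_a age_std [confound edges]
       + N(0, edge_sd)
```

Defaults are chosen once as desk-scale realistic values: baseline 0.3
and between-subject `edge_sd` 0.25 (typical Fisher-z magnitudes),
`score_sd` 1 (so the latent-to-score correlation is about 0.7),
`beta` 0.5, confound leakage 0.3 per SD of motion/age on the planted
edges, ages uniform on 36–100, per-scan maximum frame-to-frame
displacement truncated-normal with mean 0.14 mm and SD 0.06 mm (so a
small, realistic fraction crosses the 0.3 mm exclusion threshold).
Absent confound leakage, the population correlation between a planted
edge and the latent propensity is `beta / sqrt(beta^2 + edge_sd^2)`;
confound terms add their variance to the denominator — the closed form
the generator is tested against.

What the generator does **not** emulate: spatial autocorrelation between
edges (non-planted edges are independent), hemodynamics and scan-length
effects (the optional time-series mode samples a multivariate normal
with the target correlation, after projection to the nearest positive
semidefinite correlation matrix when needed), task block structure,
site effects, and demographic covariates beyond age and sex. Passing
tests therefore demonstrate the *machinery* — selection calibration,
consensus recovery, transfer asymmetry, segregation contrasts — under a
clean linear-Gaussian world, not performance on real connectomes.

## Numerical choices

* Correlations are clipped to |r| <= 1 − 1e−7 before the Fisher
  transform, so degenerate series give large finite weights.
* Edge-indexed vectors use one fixed ordering everywhere: the row-major
  strict upper triangle, (1,2), (1,3), …, 0-based in files.
* Inside a fit, fold-level partial correlations are computed from
  precomputed full-sample cross-moments minus the test fold's
  contribution (an exact algebraic identity with residualization on the
  training rows, with covariates standardized for conditioning); the
  direct residualization path (`select_edges`) is the reference
  implementation and the two are tested to agree to 1e−10. A fold whose
  covariate cross-product is singular falls back to the direct path.
* Degenerate folds — no edges pass `alpha`, or the summed connectivity
  has zero training variance — predict the training-mean score and are
  flagged, keeping the iteration ensemble intact.
* The median iteration is the lower median (rank ⌈n/2⌉) with ties broken
  by lower iteration index; undefined (degenerate) performance ranks
  lowest. All of this makes the fit a pure function of (data, config,
  seed).
* Missing motion values exclude the subject (reason `"missing-motion"`),
  the conservative reading of a missing-data exclusion rule.
* Pipeline stage seeds derive from the global seed by a fixed polynomial
  byte hash of the stage labels modulo 2^31 − 1 (`derive_seed`), so any
  stage subset re-runs reproducibly.

## Problem sizes in the shipped tests

The validation suite exercises the full pipeline at sizes chosen to
keep a complete run at desk scale while leaving the statistical checks
well-powered: oracle-equivalence checks use 100 random instances per
statistic; null calibration uses 120-subject cohorts on a 60-node atlas
(100 iterations for selection-rate calibration; 50 cohort replicates
with 200 permutations each, observed and permuted runs sharing a
reduced iteration count so the null stays exchangeable); signal
recovery plants 20 edges per sex at `beta = 0.5` in 200-subject-per-sex
cohorts on the full 268-node atlas with 100 iterations. Full-scale
(1,000-iteration, 1,000-permutation) settings are the package defaults
and the `profile = "paper"` pipeline preset.

## Limitations

**The consensus rule controls fold-assignment instability, not sampling
noise.** Within a fixed dataset, an edge whose full-sample partial
correlation happens to exceed the selection threshold is selected in
most folds of most iterations, because every fold resamples the same
subjects; the 2-of-5-folds-in-40% filter therefore retains chance edges
at a rate close to the selection `alpha` itself (we measure about 1% of
all edges on signal-free synthetic cohorts, matching `alpha = 0.01`).
With E edges, a consensus matrix should be expected to contain roughly
`alpha * E` edges that reflect sampling accidents of that particular
cohort rather than population signal — about 360 of the 35,778 edges of
a 268-node parcellation. Planted-signal recovery in the validation
suite is consequently excellent in sensitivity but, when the planted
set is small, the edge-level false-discovery proportion of the
consensus is dominated by this `alpha * E` term, and no setting of the
consensus thresholds at a fixed `alpha` can push it below it. Consumers
of consensus edge lists should read them as "stable under fold
reassignment", not as FDR-controlled discoveries; the network-level
summaries and difference maps, which aggregate over many edges, are the
robust readout.

The consensus thresholds, selection `alpha` and iteration counts
also interact: with few iterations the 40% bar is coarse, and with very
liberal `alpha` the positive/negative sets can overlap across folds in
ways the both-sign rule must arbitrate. The association ratio with
signed weights can be non-monotone in added weight (only the
non-negative case has the monotonicity guarantees above), and near-zero
denominators are undefined by design. Nothing in the package addresses
preprocessing of raw imaging data; inputs are assumed to be cleaned
node time series or validated connectivity matrices.
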