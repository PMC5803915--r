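---
title: "Methods: network construction, metrics, statistics and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network construction, metrics, statistics and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ratconnectome)
```

This vignette documents the models the package implements, the conventions
and numerical choices behind them, what the synthetic cohort generator does
and does not emulate, and the design decisions that were genuinely open.

## Nodes: the parcellation table

Network nodes come from a region table: one row per hemisphere-region with
a 1-based structural index, an optional functional index, a tissue class
and a volume in mm³. The packaged table describes a 76-region whole-brain
rat parcellation of which 54 gray-matter regions serve as functional nodes;
regions made up only of white matter carry no functional index because the
BOLD signal of interest is confined to gray matter. Internally node ids are
0-based and ordered by the table's index, which fixes the row/column
convention of every adjacency matrix; file formats keep the printed 1-based
indexing. The packaged volume column is synthetic — the source parcellation
publishes no volumes — so fiber-density weights computed from it are
internally consistent but not anatomically meaningful; real analyses must
supply measured volumes. Whether region volumes should be expressed in
voxels or mm³ is not settled by any source we follow; the package
standardises on mm³, which only rescales fiber densities by a constant and
therefore leaves every group comparison unchanged.

## Structural connectomes

An edge exists between two regions when at least one streamline joins them.
Streamlines carry no anatomical direction, so the unordered endpoint pair
defines the edge and matrices are symmetric by construction; streamlines
starting and ending in the same region are dropped because all graph
metrics assume a zero diagonal. Three weightings:

- **binary** — presence/absence;
- **FA-weighted** — the unweighted arithmetic mean of the per-streamline
  mean FA over the pair's streamlines (whether the original analyses
  length-weighted this mean is unstated; the unweighted mean is recorded
  as our choice);
- **FD-weighted** — fiber density, `1/(V_I V_J) * sum(1/l(s))`, in units of
  mm⁻¹ per mm⁶ with no rescaling. Doubling both volumes divides every
  weight by four; this scaling law is asserted in the tests.

Streamlines whose endpoints fall outside the declared node range are
rejected at validation time rather than silently dropped, because they
indicate an upstream tractography/parcellation mismatch.

## Functional connectomes

Preprocessing applies, per regional signal: linear detrend, band-pass
(default 0.01–0.1 Hz), nuisance regression, z-score. Choices worth
recording:

- The band-pass is a hard frequency-domain mask, chosen because it is
  reproducible bit-for-bit; no filter family is implied by the method
  description we follow, which names only the band.
- Detrending and the band mask are both orthogonal projections of the
  time-domain signal; the package applies the exact projection onto the
  intersection of their target subspaces (computed in closed form from the
  band image of the trend basis). This makes preprocessing idempotent:
  re-running it on its own output reproduces the input to machine
  precision, a property the test suite asserts at 1e-8. Trend directions
  the mask already annihilates (the DC component) are excluded from the
  constraint, which keeps the projection well-defined.
- Nuisance regressors (motion parameters, mean WM and CSF signals) are
  detrended and filtered identically before the regression, so the
  residual step cannot reintroduce out-of-band energy.
- A region whose signal is constant after these steps has no defined
  correlation; this is an error naming the region, not a silent drop.
- Whether detrending should be linear or polynomial is unstated upstream;
  linear is implemented.

Partial correlations condition on **all** other regions jointly (the
standard reading), via the inverse of the sample correlation matrix:
`pc_ij = -P_ij / sqrt(P_ii P_jj)`. At the default design — 54 regions,
600 samples — the matrix is well conditioned; for stress cases a ridge
`1e-6 * trace(R)/N * I` is added when the condition number exceeds 1e10,
and disabling the ridge turns that situation into an error. Negative
partial correlations are excluded *before* the Fisher z-transform; since
`z > 0` iff `r > 0`, the two possible orders coincide, and the pre-transform
exclusion is numerically cleaner. The binary functional connectome is the
indicator of the weighted one.

## Graph metrics

- **Shortest paths** use edge length `1/weight` (the standard inverse
  mapping; binary graphs reduce to hop counts). This choice is recorded
  prominently because it enters every weighted integration metric.
  Unreachable pairs have infinite distance and contribute zero efficiency
  rather than raising an error, since sparse functional graphs can be
  disconnected.
- **Global efficiency** is the mean inverse distance over ordered pairs.
- **Nodal efficiency** is the global efficiency of the subgraph induced by
  a node's neighbours (the node excluded), i.e. the local-efficiency
  reading of "the efficiency of the subnetwork associated with a node".
  The alternative closeness-type reading (mean inverse distance from the
  node) cannot be reconciled with the subgraph definition; it is exposed
  as `definition = "closeness"` but is not the default.
- **Clustering** is the triangle fraction on binary graphs and the Onnela
  geometric-mean formula on weighted graphs, with weights normalised by the
  graph maximum — the dominant convention in the brain-network literature.
  With all weights equal it reduces exactly to the binary value, which the
  tests assert.
- Degree counts any nonzero weight; no threshold is applied, matching the
  binary-from-weighted construction.
- Global degree/strength/local efficiency/average clustering are
  arithmetic means of nodal values; global efficiency is computed once on
  the full graph.

Every metric is checked against independent oracles: igraph shortest
paths, materialised neighbour subgraphs, and explicit triangle
enumeration, exhaustively for all graphs on up to 5 nodes, on random
6-node graphs across the density range, and on random weighted graphs up
to 30 nodes. Exhaustive enumeration stops at 5 nodes (1,099 graphs
per metric route) and samples 300 graphs at 6 nodes; this keeps the suite
fast while the oracle-equality assertion itself stays exact on every
enumerated graph.

## Group statistics and screening

Both a Kruskal–Wallis rank test and a Gaussian identity-link GLM
`value ~ group + age` are reported for every metric. The GLM exists
because the study design confounds scan age with group: animals scan after
reaching a behavioral criterion, and the slower-learning transgenic group
scans older. The tests include a simulation in which the metric declines
with age and has no group effect; the naive rank test is anticonservative
there while the age-adjusted GLM holds its level. The GLM family/link is
not specified by the method description we follow; Gaussian-identity is
the natural choice for continuous metrics at this cohort size. If ages are
constant the covariate drops and the model reduces to a two-sample
comparison (the tests assert exact agreement with a pooled-variance
t-test); if group is perfectly collinear with age the fit errors naming
the collinearity rather than reporting an uninterpretable coefficient.

FDR correction is Benjamini–Hochberg, applied per (connectome kind,
metric, test) family across regions — the "per metric family" reading of
regional multiple-comparison correction. Whether the original analysis
pooled hemispheres or metrics into one family is unstated; per-family is
the default and the `group_metric_tests()` surface makes other groupings
easy to apply downstream. Global metrics form singleton families. The
Kruskal–Wallis p-value uses the 1-df chi-square approximation, with an
exhaustive-permutation mode (`exact = TRUE`) used by the test suite at
small n.

Behavior screening reports Spearman correlations and flags |r| > 0.7
without multiplicity correction, exactly as such screens are convention-
ally reported; the flag threshold is strict inequality.

## The synthetic cohort generator

The generator emulates the study conditions the pipeline was built for:
9 animals per group, the 76/54 parcellation, 600 BOLD samples at TR = 2 s,
band 0.01–0.1 Hz, control scan ages 151.11 ± 12.06 days and transgenic
181 ± 32.6 days (the transgenic group trains longer and scans later, so
the age confound is generated, not assumed away).

No streamline-count, FA or BOLD covariance statistics are published for
the data it stands in for, so those parameters are generator calibrations,
chosen once for pipeline testability and documented here:

- Region centroids are uniform in a 16 × 10 × 8 mm box; connection
  probability decays with centroid distance (scale 5 mm) and is normalised
  to a mean edge density of 0.35; streamline counts are
  `1 + Poisson(12 · exp(-d/10))`; lengths are the centroid distance times
  a tortuosity factor in [1.05, 1.6]. Fiber densities therefore span
  realistic orders of magnitude rather than copying unpublished values.
- Per-connection FA is Normal(0.45, 0.08) truncated to [0.05, 0.95],
  shared across the cohort as "anatomy"; each subject applies a global FA
  scale Normal(1, 0.05) — the between-animal variability the group tests
  work against — and transgenic subjects multiply FA by `1 - fa_effect`
  (default 0.15). At these settings the planted effect is detected on
  FA-weighted average strength with power above 0.8 at 9 + 9, which is a
  calibration target of the generator, not an empirical claim.
- BOLD series are Gaussian with a planted sparse precision (8 % of pairs
  at partial correlation 0.2, kept positive definite by construction),
  band-limited by the same mask as preprocessing, then wrapped in a
  baseline, a linear drift, and motion/WM/CSF contributions so that
  preprocessing is exercised, not bypassed.
- Behavioral coupling is induced by a Gaussian copula on the ranks of a
  named network metric (default: fiber-density average strength vs total
  training sessions at Spearman −0.72), so the generator controls exactly
  the quantity the screen measures; the latent correlation uses the
  standard `2 sin(π ρ_s / 6)` conversion. Group shifts (transgenic train
  longer, complete fewer trials) are added on top.
- `plant_regional_effect()` perturbs a single region's incident
  streamlines (FA or length) or its BOLD coupling gain for one group and
  records the change in the ground-truth manifest; plants commute and a
  zero delta is a no-op.

What the generator does **not** emulate: voxel-level imaging, scanner
physics, tractography biases (gyral bias, distance-dependent FA along a
streamline), non-Gaussian BOLD dynamics, hemodynamic lags, or the
behavioral task's trial-by-trial dynamics. Passing tests therefore
demonstrate that the pipeline recovers effects planted at the level of its
own inputs — streamline records and regional series — not that it would
recover them from raw images.

## Problem sizes used by the checks

The test suite and the acceptance script scale their simulations to run
comfortably on one CPU: graph-metric oracles run exhaustively to 5 nodes
and on random graphs to 30 nodes; the GLM null calibration uses 1,000
simulated 9 + 9 cohorts; planted-effect direction recovery uses 200
replicate cohorts on a 20-region parcellation with 60-sample series (the
structural pathway under test does not involve the series length); the
coupling-recovery check uses one 30 + 30 cohort at target Spearman −0.85.
These sizes are the package's own choices and are stated here so they can
be scaled up deliberately.

## Known limitations

- Fiber density inherits the synthetic volumes of the packaged table
  unless real volumes are supplied.
- The partial-correlation estimator assumes more effective samples than
  regions; heavily filtered short series at large parcellations need the
  ridge guard, which biases estimates toward zero slightly.
- The weighted clustering and inverse-weight path-length conventions are
  choices among several in circulation; comparisons across packages should
  confirm conventions match before comparing numbers.
- The report stage lists findings; it does not attempt effect-size
  meta-summaries or longitudinal modelling, which are out of scope.
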