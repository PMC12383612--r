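---
title: "Methods: presence-background maximum entropy, model tuning, and habitat dynamics"
author: "maxentSDM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: presence-background maximum entropy, model tuning, and habitat dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maxentSDM)
```

`maxentSDM` implements a complete species-distribution-modeling workflow
for presence-only occurrence data on regular longitude/latitude raster
grids: spatial thinning, predictor screening, a from-scratch
maximum-entropy (Gibbs) density model with the five standard feature
classes, regularization-multiplier/feature-combination tuning, habitat
suitability classification with spherical areas, change matrices between
climate periods, and suitability-weighted centroid migration. The
motivating application is projecting habitat shifts of a bioenergy grass
across China under warming scenarios, but every stage is generic. This
vignette records the model, its assumptions, the tunable parameters, and
the design decisions that were genuinely open.

## The presence-background model

Presence-only data cannot identify prevalence; what they do identify is
a probability density over landscape cells. The model is the Gibbs (log-
linear) density

$$ q_\lambda(x) \;=\; \frac{\exp\big(\sum_j \lambda_j f_j(x)\big)}{Z(\lambda)},
\qquad Z(\lambda) = \sum_{x \in \mathrm{background}} \exp\Big(\sum_j \lambda_j f_j(x)\Big), $$

the unique maximum-entropy distribution matching the presence means of
the features \(f_j\). Fitting maximizes the equivalent convex penalized
log-likelihood

$$ \ell(\lambda) \;=\; \frac{1}{m}\sum_{i=1}^{m} \sum_j \lambda_j f_j(x_i)
   \;-\; \log Z(\lambda) \;-\; \sum_j \beta_j |\lambda_j|, $$

where \(m\) is the number of presence records and the background is a
uniform random sample of valid cells (capped at 10,000 by default;
presence cells are not excluded). The L1 penalties \(\beta_j\) make the
solution sparse and control overfitting.

**Features.** Each raw predictor is affinely scaled to \([0,1]\) by its
background minimum/maximum (the scaling is stored and reused verbatim
for presence and projection data). The classes are linear (L), quadratic
(Q), pairwise products (P), forward/reverse hinges (H) at evenly spaced
interior knots, and step thresholds (T). Knots default to 30 per
variable per direction on a fixed uniform grid, a deterministic stand-in
for data-driven knot placement; tests and the shipped pipeline runs use
10 (and 5 in the quickest configurations) because on 2,000-cell
backgrounds with ~50 presences the fitted surfaces are visually and
numerically indistinguishable while fits are several times faster.

**Penalty schedule.** \(\beta_j = \mathrm{RM}\cdot
\beta_{\mathrm{class}}(m)\cdot \mathrm{sd}_{\mathrm{bg}}(f_j) / \sqrt{m}\),
with the published per-class interpolation tables
(linear/quadratic 1.0 at \(m\le 10\) to 0.05 at \(m\ge 100\); hinge 0.5;
threshold 2.0 to 1.0; product 2.6 to 0.25) linearly interpolated in
\(m\) and clamped at the table ends. The regularization multiplier RM
scales all penalties globally; RM and the feature combination (FC) are
the two tuned hyperparameters.

**Solver.** Cyclic coordinate descent. Each coordinate takes a Newton
step on the smooth part of the objective (gradient = presence mean minus
background expectation; curvature = background variance of the feature
under \(q_\lambda\)), soft-thresholded by \(\beta_j\), then backtracks
on the exactly evaluated objective so every accepted step is an ascent
step. The background weights \(w = e^{\eta}\) are maintained
incrementally (one `exp` per update, with periodic renormalization
against overflow), and between full sweeps the active (nonzero) set is
iterated to internal convergence, as in coordinate-descent lasso
solvers. Stopping: maximal KKT violation below `tol = 1e-6`, or two
consecutive sweeps improving the objective by less than 1e-8, or
`maxit = 200` sweeps. The progress criterion matters for low-RM hinge
models on small samples, where a near-separable feature lets the
objective creep indefinitely at numerically irrelevant rates. On
problems with one or two features the solver agrees with dense grid
search of the objective to three decimals (tested).

**Outputs.** `raw` is \(q_\lambda\) renormalized over the prediction
domain (sums to 1). `logistic` is the standard 0–1 index at prevalence
\(\tau = 0.5\): \(\sigma(\eta(x) - \log Z + H)\) with \(\log Z\) and the
entropy \(H\) of the fitted background distribution frozen at their
training values, so the uniform model scores exactly 0.5 everywhere.
`cumulative` is 100 times the raw mass at or below the cell's raw value.
Clamping truncates each predictor to its training range before feature
evaluation; the pipeline clamps when projecting onto scenario layers and
not on the training domain.

**Diagnostics.** Percent contribution credits each accepted coordinate
update's objective gain to the underlying variable (product features
split the credit equally) and normalizes to 100%. Because the credit is
path-dependent it is a heuristic, the same one users of the reference
implementation rely on; the jackknife (refit with only / without each
variable, reporting regularized training gain, i.e. mean presence
log-density over the uniform model minus the penalty) is the
order-independent complement. Response curves sweep one variable across
its training range with the others fixed at background means;
`optimalRange()` reads off the interval where the curve stays at or
above a probability threshold (0.5 by default), interpolating linearly
at the crossings.

## Tuning and evaluation

Candidates form the grid of nine feature combinations (L, H, LQ, LQH,
LQHP, LQHPT, QHP, QHPT, HPT) by eight multipliers (0.5–4.0 in 0.5
steps). Per candidate:

* **AICc** \(= 2k - 2L + 2k(k+1)/(m-k-1)\), with \(k\) the number of
  nonzero coefficients of the full-data fit and \(L\) the sum of
  presence log-densities. The density is normalized over the union of
  background and presence rows (the study-landscape convention). This
  matters: normalizing over the background alone allows heavily
  parameterized hinge/product candidates to push presence densities
  above any background cell's and win the comparison on an artifact.
  AICc is undefined (and the candidate excluded from the minimum) when
  \(m - k - 1 \le 0\).
* **OR10**, the 10-percentile omission rate: threshold at the
  \(\lceil 0.1\,n_\mathrm{train}\rceil\)-th smallest training presence
  score, rate = fraction of held-out presences strictly below it.
* **AUC.diff** = training AUC minus test AUC (overfitting indicator),
  with AUC the rank-based Mann–Whitney estimator (half credit for ties)
  against the background as the negative class.

OR10 and AUC.diff are averaged over a presence partition — random
k-fold by default, with repeated 75/25 subsampling available. Selection
minimizes Delta.AICc (= AICc minus the grid minimum, so the best
candidate is exactly 0), breaking ties by lower OR10, then lower
AUC.diff, then fewer parameters; the tie-break chain is a package
choice, since only the metrics themselves are standard. The final model
protocol is 10 random 75/25 replicates; the reported suitability layer
is the cell-wise mean of the replicate logistic layers, and the mean ±
sd training AUC is read against the conventional five bands (0.8–0.9 =
"high prediction accuracy").

## Habitat classification, change and centroids

Suitability \(P\) is classified with fixed half-open bins: non
\([0,0.1)\), low \([0.1,0.3)\), medium \([0.3,0.5)\), high
\([0.5,1]\). A Jenks natural-breaks utility (exact Fisher–Jenks dynamic
programming) is provided for exploratory use, but the operative
classifier is the fixed thresholds — the workflow this package
reproduces names Jenks yet operates with these numeric bounds.
Binarization is inclusive: suitable iff \(P \ge 0.1\).

Cell areas are spherical: \(R^2\,\Delta\lambda\,(\sin\varphi_t -
\sin\varphi_b)\) with \(R = 6371.0088\) km, constant within a grid row.
Between a current and a future binary map, per-cell transitions are
gain (0→1), loss (1→0), retention (1→1); rates divide by the union
(retained + lost + gained), the only denominator under which the three
rates sum to 100% and which reproduces every published rate in the
reference tables to within 0.006 percentage points (tested to ±0.01).

Centroids are suitability-weighted mean centers over cells with
\(P \ge 0.1\), weight \(P \times\) cell area, averaged directly in
lon/lat (the planar mean-center convention; the domain spans tens of
degrees at mid-latitudes, where this matches projected mean centers to
well under coordinate precision). Per-band unweighted centroids are
available via `weighted = FALSE`. Track segments report haversine
distance, the spherical initial bearing (computed from the standard
atan2 form; at integer-degree precision this is indistinguishable from
any other earth model) with an 8-way compass label, and velocity =
distance / 20 years — the inter-period spacing implied by published
velocity/distance pairs (150 km ↔ 7.5 km/yr). Cumulative displacement
is first-to-last centroid distance.

## The synthetic data generator

Real predictor rasters and curated occurrences are deliberately out of
scope; the generator supplies statistically controlled stand-ins so
every stage is testable offline:

* **Layers**: white Gaussian noise convolved with a Gaussian kernel
  (`corrLength` cells, replicated edges), rescaled to realistic ranges
  (e.g. an elevation-like 1–4178 m layer). This gives qualitatively
  correct smooth spatial structure with one interpretable knob; it does
  not emulate variograms, anisotropy, cross-layer correlation structure,
  or terrain morphology.
* **Truth**: a linear (optionally linear+quadratic) Gibbs density over
  the scaled layers, normalized to mass 1 over valid cells — the same
  family the model fits, which is exactly what parameter-recovery
  testing requires.
* **Occurrences**: cells drawn proportionally to the truth; each draw
  emits a small cluster of jittered points, emulating the duplicated,
  spatially clustered records of herbarium/database searches.

The reference study fixture is a 60×90 grid at 2.5 arc-minutes with 8
layers named after the retained bioclimatic/terrain predictors, truth
coefficients (bio11 = 5, bio13 = 3, elevation = −4), and 50 draws × 3
points (150 raw records, thinning to ~50 spatially independent cells —
the data scale of the motivating study). The pipeline's default
scenario set perturbs the winter-temperature layer additively (three
pathways × three periods, +1.0 to +4.5 °C) on top of a north–south
gradient, so warming demonstrably shifts the suitable band and its
centroid poleward. Passing tests on these fixtures shows the machinery
is correct and internally consistent; it says nothing about how well a
maxent model describes any real species, nor about realism of future
climate fields.

## Numerical choices and degenerate inputs

* Thinning distance is great-circle to the cell center; ties broken by
  smallest record id; output in row-major scan order. At 2.5′ resolution
  the haversine argmin coincides with the projected-Euclidean argmin.
* Records in cells where any layer is no-data are excluded as lacking
  complete habitat information, and reported, not silently dropped.
* Spearman correlations at occurrence cells by default (whole-region
  optional); undefined correlations (constant layers) count as |r| = 0
  for pruning. Pruning is greedy largest-|r|-first, strictly above the
  0.75 threshold, dropping the lower-contribution member; remaining
  ties are resolved lexicographically, so screening is deterministic.
* Constant variables keep a zero linear column; their Q/H/T features
  are dropped with a warning.
* All-flat elevation yields slope 0 and aspect sentinel −1 everywhere.
* Classification errors on values outside [0,1]; masked cells propagate
  as NA through classification, change and centroids.
* Every stage seed is derived from the master seed and the stage name,
  so stages are independently reproducible and an identical
  configuration reproduces byte-identical summary tables.

## Problem sizes used by the shipped runs

The test suite runs on 30×40 to 60×90 grids with backgrounds of
300–2,000 cells, tuning grids of 2×2 to 3×3 candidates, and replicate
counts of 3–10; the acceptance script runs the full 60×90 fixture with
a 4 FC × 4 RM grid, 2,000 background cells, 3-fold tuning partitions
and 10 final replicates, plus a 5,000-presence density-recovery fit.
These sizes were chosen so a complete run takes minutes on one CPU;
all of them are configuration fields, and the full 9×8 grid with
10,000 background cells is the package default.

## Known limitations

* Percent contribution inherits the path-dependence of coordinate
  descent credits; use the jackknife for order-independent statements.
* The logistic output assumes prevalence 0.5; reported "suitable
  fractions" of a landscape depend on that convention and on the 0.1
  threshold, not only on the data.
* Background-vs-landscape normalization is a real degree of freedom in
  AICc for presence-background models; both are exposed, the landscape
  union is used for selection.
* Hinge/threshold knots on a fixed uniform grid slightly coarsen the
  fit relative to data-driven knots at equal counts.
* The generator produces smooth isotropic fields; screening behaviour
  on strongly collinear real climate stacks is exercised only through
  constructed correlation structures in the tests.
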