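---
title: "Maximum-entropy niche modelling with nichecast: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Maximum-entropy niche modelling with nichecast}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nichecast)
```

## The model

`nichecast` fits presence-background species distribution models by the
maximum-entropy principle. Given presence records and a background sample of
landscape cells, the fitted distribution over background cells is the Gibbs
form

$$q_\lambda(x) \;=\; \frac{e^{\eta(x)}}{Z_\lambda}, \qquad
  \eta(x) = \sum_j \lambda_j f_j(x), \qquad
  Z_\lambda = \sum_{x \in \mathrm{background}} e^{\eta(x)},$$

the distribution of maximum entropy among those matching the presence means
of the features $f_j$ (up to the regularization slack). The coefficients
minimize the L1-penalized objective

$$J(\lambda) = -\frac{1}{m}\sum_{i \in \mathrm{presences}} \eta(x_i)
  + \log Z_\lambda + \sum_j \beta_j |\lambda_j|,$$

with per-feature penalties $\beta_j = rm \cdot \beta_{class}(m) \cdot s_j /
\sqrt{m}$, where $m$ is the presence count, $s_j$ the feature's standard
deviation over presences, $\beta_{class}$ the per-class default schedule
(interpolation tables for linear/quadratic/product; a constant 0.5 for
hinge), and $rm$ the regularization multiplier. The tables live in
`nichecast:::beta_class_tables` and are pluggable.

Features are built from the background sample: scaled linear terms,
their squares, pairwise products, and forward/reverse hinges at 50
background quantiles per variable per direction (configurable via
`n_knots`). All features lie in $[0,1]$ on calibration data.

Fitting is cyclic coordinate descent with soft-thresholding, in compiled
code: each coordinate takes a prox-Newton step from the gradient and
curvature of the smooth part under the current Gibbs weights, backtracking
until the exact objective decreases, so the objective is monotone.
Convergence is declared when a full cycle improves the objective by less
than `tol` (default $10^{-5}$, with at most 500 cycles) — the same
convergence parameters commonly used for this model family. Numerical
safety: the background weights are periodically re-offset to avoid
overflow, curvature is floored at $10^{-12}$, and a zero-variance feature
keeps a zero coefficient (its penalty falls back to the background
standard deviation).

The mapped output is the cloglog transform
$c(x) = 1 - \exp(-e^{H} q(x))$, where $H$ is the entropy of the fitted
distribution; it is strictly increasing in $q$, lies in $[0,1]$, and for
the null model (all $\lambda_j = 0$) equals $1 - e^{-1}$ everywhere.

## The analysis chain

The pipeline runs, in order: record cleaning (coordinates present and in
range, collection year present and at least `min_year = 1965`, inside the
range polygons, off land), one record per grid cell, spatial thinning to
5.5 km, masking of the predictors to the calibration (M) region,
collinearity pruning, contribution pruning, a candidate-model grid search,
a final bootstrap-replicate fit, scenario projection with clamping,
thresholding, and the change/centroid/protected-area summaries.

**Predictor selection.** Pairwise Pearson correlations are computed over
the masked calibration cells (the modelling domain). While any pair of
kept variables reaches $|r| \ge 0.7$, the member of the most-correlated
pair with the larger variance inflation factor is dropped (ties drop the
later variable in input order, making the loop deterministic). A
preliminary model (classes `lqph`, $rm = 1$) is then fitted ten times with
different background seeds, and variables averaging at most 1% contribution
are dropped. What varies across the ten preliminary runs is the background
sample: the run-to-run variation of a default-settings model is dominated
by that sample, and the occurrence set is deliberately held fixed.

**Calibration.** The default grid crosses eight regularization multipliers
(0.5–4.0 by 0.5) with all 15 nonempty subsets of the four feature classes
(120 candidates). Each candidate, fitted on a seeded 70/30 split, must (1)
be statistically significant by partial ROC (500 iterations, 50% bootstrap
resampling of the test presences with replacement), (2) keep its omission
rate at $E = 5\%$ at most 0.05, and (3) sit within 2 AICc units of the best
AICc among candidates passing (1) and (2) — that reference pool, rather
than all candidates, defines $\Delta$AICc, mirroring the sequential
narrative of the selection procedure. The omission threshold is the
$\lceil E \cdot n \rceil$-th smallest training score (inclusive); quantile
conventions differ between implementations, so this one is pinned by
tests. AICc standardizes the raw scores over all calibration cells to sum
to one, takes the log-likelihood at the occurrence cells, and counts
parameters as nonzero coefficients; it is undefined when $n \le k + 1$.
The partial-ROC area ratio integrates the (proportional area, sensitivity)
curve by trapezoid over the unique prediction values (capped at 1,000
quantile thresholds), restricted to sensitivity $\ge 1 - E$, against the
1:1 line over the same support — a definition under which the null line
scores exactly 1.

**Projection and extrapolation.** Projection clamps each variable to its
calibration range before feature evaluation ("extrapolation and
clamping"): clamping at the variable level is the simplest consistent
choice and is equivalent to feature-level clamping for linear, quadratic
and hinge features. The mobility-oriented parity (MOP) map standardizes
variables by calibration mean/sd and reports, for each scenario cell,
one minus its mean Euclidean distance to the nearest 10% of calibration
cells, scaled by the maximum such distance; any cell with a variable
outside the calibration min–max is strict extrapolation. The 10% subset
fraction is not fixed by the methodology this mirrors and is configurable.

**Binary maps and accounting.** The binarization threshold maximizes
training sensitivity plus specificity (MTSS) over all unique pooled
scores; equality at the threshold counts as suitable, and ties between
thresholds return the smallest — both conventions are pinned by tests.
Change maps code cells as never-suitable, lost, gained, or maintained;
areas use exact spherical cell areas on the authalic sphere
($R = 6371.0088$ km, $A = R^2 \Delta\lambda (\sin\varphi_{top} -
\sin\varphi_{bot})$), accurate to well under 0.3% of ellipsoidal values at
these scales. Percentages follow two conventions: category areas are
relative to the *current* suitable area, and the total change is
$(future - current)/current$. Protected-area percentages (both inside and
outside) are also relative to the current total — the convention the
published overlap tables use, verified arithmetically in the tests.
Centroids are area-weighted means of suitable cell centers (a guard
refuses dateline-crossing extents); shifts report geodesic WGS84 distance
and initial bearing, with bearing 0 by convention for a zero shift.

## Spatial plumbing

Rasters are plain-text ESRI ASCII grids with a `.prj` sidecar; the reader
refuses projected coordinate systems by name. Polygons are GeoJSON.
Cell membership everywhere — masking, protected-area overlap, synthetic
coverage — is by cell center, so area numbers are reproducible to the
cell. Grids are geographic WGS84 with the origin at the outer north-west
corner; rows increase southward. Aligning a stack unions the per-layer
nodata footprints so every layer shares one mask; layers on a different
grid can be bilinearly resampled (appropriate for continuous
climatological fields, the only kind the pipeline models).

## The synthetic landscape and what it does (not) show

`make_landscape()` generates seeded, spatially autocorrelated standardized
Gaussian fields (white noise low-pass filtered by FFT, correlation length
8 cells) on a 200 × 200 grid of 0.05° cells straddling the equator. The
equatorial placement makes the known-answer translation test clean: a 1°
eastward shift of the driving fields is ~111 km everywhere on the grid.
The first variable blends in a domain-centered dome (weight 0.7),
emulating a bounded physical driver such as shelf bathymetry; this keeps
the species' core habitat in the domain interior, as for a
continental-shelf endemic, so translated scenarios do not run the habitat
off the mapped domain. The truth surface is
$s(x) = \mathrm{logistic}(-2 + 2 v_1 + v_2 - 2 v_2^2)$: monotone in the
productivity-like axis $v_1$, unimodal in the temperature-like axis $v_2$
(optimum at $v_2 = 0.25$), with three further inert variables so
contribution pruning and jackknife analyses have known winners and losers.
These coefficients make roughly 13% of the landscape suitable — the order
reported for restricted-range shelf species, whose suitable habitat
typically covers around a seventh of the accessible region. Presences are sampled
with probability proportional to suitability and jittered within cells;
future scenarios translate the driving fields by whole cells (edge values
replicated) and/or add trends, leaving static fields untouched; synthetic
protected areas are random rectangles grown until they cover 25% ± 5% of
the suitable area, the order of the real system's current protection.

Passing tests on this landscape show that the estimator recovers a known
smooth unimodal niche from presence-only samples of moderate size, that
the selection statistics behave as defined, and that the change/shift
accounting is exact. They do not show robustness to sampling bias
(supported via `bias_raster` but not part of the standard conditions),
detection error, niche-environment interactions absent from the truth,
non-equilibrium occupancy, or the spatial dependence structure of real
climatological layers.

## Design choices made where the design was open

- **Thinning.** The published thinning approach is a randomized heuristic;
  repeated max-degree removal cannot guarantee a maximum retained set, and
  we found 10-point instances where it strictly loses a record. Small
  conflict graphs (≤ 20 records) are therefore solved exactly by
  branch-and-bound; larger ones use the seeded heuristic with
  `n_attempts = 10`. Thinned output always satisfies the 5.5 km floor.
- **Dedup-then-thin.** "One record per 0.05° pixel" and "a 5.5 km radius"
  are both honored by deduplicating per cell first and then enforcing the
  distance floor.
- **Percent contribution** is defined by refit-drop — the loss of
  regularized training gain when a variable's features are removed and the
  model refit, normalized to 100 — rather than the original per-iteration
  path-attribution heuristic, which depends on optimizer internals and is
  not reproducible across fitting algorithms.
- **Background** is a uniform sample without replacement of calibration
  data cells, capped at 10,000, presences not excluded, seeded.
- **Replicates** bootstrap the presences (with replacement, same size)
  with the background held fixed; replicate type for the original analyses
  is stated as bootstrap over occurrences, and varying the background too
  would conflate two sources of variation.
- **AICc occurrences.** Candidate AICc uses the train-fitted model scored
  at all (train + test) occurrences, matching a selection step that ranks
  parsimony against the full occurrence evidence.
- **Equal-area question.** Published area totals at this scale could come
  from an equal-area projection or spherical integration; exact spherical
  cell areas were chosen as the reproducible option, and the acceptance
  checks rest on the percentage identities, which are projection-free.

## Problem sizes and determinism

The test-suite simulations use 40–70 cell grids with reduced backgrounds
and knot counts; the standard recovery scenario uses the full 200 × 200
grid, 500 presences, a 10,000-cell background and `lqh` features at
$rm = 1$, which fits in seconds. Every stochastic step — background
sampling, splits, bootstrap, thinning tie-breaks, partial-ROC resampling,
the landscape itself — is a pure function of its seed, and the pipeline
derives all stage seeds from one master seed, so a run is reproducible
from a single integer.

## Known limitations

- No categorical (factor) predictors and no threshold feature class.
- Geographic (lon/lat) rasters only; no reprojection, no NetCDF/GeoTIFF.
- Polygon overlap is by cell center; partial-cell apportionment at polygon
  boundaries is not attempted, so protected-area totals carry up to one
  cell of edge error per boundary cell.
- The MOP similarity scale is relative to the most dissimilar non-strict
  cell of the scenario under analysis, so values are comparable within one
  scenario, not across scenarios.
- Study extents crossing the ±180° meridian are refused rather than
  handled.
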