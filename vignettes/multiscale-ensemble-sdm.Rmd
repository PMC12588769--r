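---
title: "Methods: multi-scale ensemble distribution modeling in scalesdm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-scale ensemble distribution modeling in scalesdm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scalesdm)
```

## The model

`scalesdm` treats habitat suitability as a presence/pseudo-absence
classification problem on a regular metric grid. The distinctive step is
that predictors enter the model not at their native resolution but at a
*characteristic scale*: each continuous variable is replaced by its focal
mean, and each land-cover class by its focal fraction, in a circular
moving window whose radius is chosen per variable. The working assumptions
are:

* occurrences are a presence-only sample whose intensity increases with
  suitability, contrasted against background points drawn uniformly from
  the study grid;
* the species–environment relationship is stationary in space and time
  (the same fitted response is projected onto future predictor stacks);
* the grid is projected and metric, so window radii and areas are
  well-defined in kilometres (geographic, degree-based grids are out of
  scope).

The ensemble combines five complementary learners (penalised logistic
regression, a spline GAM, an L1-penalised feature-expanded logistic model
of the MaxEnt family, random forest, gradient boosting) by the AUC-weighted
mean of all members whose cross-validated AUC exceeds 0.7. Weighting by
discrimination skill rather than equal voting lets weak members contribute
little without being silently dropped, while the 0.7 floor removes members
no better than chance-plus.

## Scale selection

For every variable and candidate radius (default 1–10 km) the package runs
a two-sided Welch *t*-test between values at presences and at background
points. Welch's unequal-variance form is used deliberately: presence and
background samples are grossly unbalanced (hundreds versus thousands) and
have no reason to share a variance. A radius is a candidate only when
p < 0.05; the characteristic scale is the candidate with the smallest
p-value, ties resolved toward the smaller radius (parsimony: the
finer-grained predictor). A variable with no significant radius is flagged
excluded — the univariate analog of "this variable does not differ between
where the species is and is not".

Collinearity is handled by a greedy pass in ascending order of each
variable's characteristic p-value: a candidate is retained only if its
absolute Pearson correlation with every already-retained variable is at
most 0.7. The greedy order makes "keep the variable with the lower
p-value" deterministic and transitive; correlations are computed once on a
seeded sample of at most 50,000 jointly unmasked cells, which stabilises
the screen without materially changing the estimates.

## Evaluation metrics

* **AUC** is computed by the Mann–Whitney rank formulation (ties count
  one half) — exact, and cross-checked in the tests against both a pair
  enumeration oracle and an independent ROC implementation.
* **TSS** is sensitivity + specificity − 1 with the inclusive rule
  (score ≥ threshold ⇒ predicted presence), reported at the maxSSS
  threshold. The threshold search is exhaustive over the unique observed
  scores, ties broken toward the smallest maximiser so the reported
  threshold is reproducible.
* The **continuous Boyce index** is the Spearman correlation between the
  predicted-to-expected presence ratio in moving suitability classes and
  the class midpoint. Defaults are 10 classes of width 10% of the score
  range. The index is defined on [−1, 1]; a value near zero means the
  prediction ranks habitat no better than chance. Two caveats discovered
  while validating it are worth recording: with few classes the null
  distribution of the rank correlation is wide (Spearman over k
  exchangeable ratios has standard deviation ≈ 1/√(k−1) regardless of
  sample size), so null-behaviour checks use a fine-grained class
  configuration; and windows with no landscape mass are dropped, with
  fewer than three usable classes returning `NA` rather than a number.

## Cross-validation design

Presences and background points are partitioned into k folds *separately*
(stratified), re-randomised per repeat, so every fold contains presences
and every record is held out exactly once per repeat. Runs are enumerated
algorithm × pseudo-absence set × repeat × fold (the defaults 5 × 3 × 3 × 5
give 225 runs). Ensemble members are the (algorithm, pseudo-absence set)
pairs, weighted by their mean cross-validated AUC and refitted on their
full data; held-out ensemble performance is computed by applying the same
weights to the members' held-out scores, so the ensemble is never
evaluated on records its members trained on. Background records are
down-weighted so total presence and background weights are equal — the
standard device that keeps fitted scores interpretable on [0, 1] under
extreme class imbalance.

## Projection, binarization and change accounting

Projection recomputes every retained variable's focal layer at its chosen
radius on the scenario stack and scores the ensemble at each jointly
unmasked cell; projecting the training stack reproduces the training map
exactly. Suitability is averaged across climate-model variants *before*
binarization, and future maps are binarized at the current-time maxSSS
threshold, inclusive (a cell exactly at the threshold is habitat). Areas
are unmasked suitable-cell counts times the nominal cell area, with no
latitude correction (the grids are metric). The derived rates are

* net change = 100 · (future − current) / current,
* turnover = 100 · (gain + loss) / (current + gain),

and two identities hold exactly by construction: future = stable + gain
and current = stable + loss. Raw values are carried at full precision;
only the report formatter rounds (percentages to one decimal, half away
from zero). When the current map is empty the rates are `NA` and flagged
rather than invented.

Trajectory (time-step) maps classify each cell over ≥ 2 periods: never
suitable, stable, expansion (one switch to suitable with no later loss),
contraction (one switch to unsuitable with no later gain), fluctuation
(any other alternation). For three periods this matches an exhaustive
enumeration of the 8 possible trajectories; for longer runs the
"single-switch" reading is the natural generalisation and is the one
implemented. The limited-dispersal variant zeroes suitable cells whose
centres are farther than a configurable buffer (default 110 km) from the
range polygon, with point-to-polygon distance computed against the
polygon edges.

## Range dynamics

The 95% minimum convex polygon drops the ⌈5%·n⌉ points farthest from the
centroid of all points (the classic home-range convention; distance ties
drop the later record, for determinism) and takes the convex hull of the
rest. Overlap fractions divide the intersection area — computed by
Sutherland–Hodgman clipping, exact for convex rings — by each polygon's
own area. Elevation shift resolves each record's elevation (its own field
if present, else the elevation layer at its cell) and reports per-period
means, their difference, and binned densities.

## The synthetic landscape: what it emulates, and what it does not

The generator produces the statistical skeleton the analysis assumes:
spatially autocorrelated terrain (Gaussian-kernel-smoothed seeded white
noise, standardised, generated on a padded grid so borders are
stationary); slope/aspect/northness/ruggedness derived from elevation by
Horn's 8-neighbour differences; temperature layers lapse-coupled to
elevation (so they correlate negatively with it, as in any montane study
area); a near-duplicate precipitation pair to exercise the correlation
screen; a temperature-seasonality layer independent of the truth; a
three-class land cover (cropland concentrated downslope, open cover
upslope, forest between); and a human-footprint layer rising toward low,
cultivated terrain. True suitability is the logistic of an intercept plus
unimodal (negative-quadratic) and linear terms in drivers focally
aggregated at known radii; occurrences are cells drawn with probability
proportional to suitability.

Default truth parameters were fixed once, by design: the forest fraction
at 7 km is the dominant driver (slope 40 on the fraction scale) with the
intercept at −30 so that suitability stays in the non-saturating regime of
the logistic. In that regime presence sampling is an exponential tilt in
the 7-km forest fraction, which is what makes the characteristic scale
identifiable at realistic sample sizes: the presence–background *t*
profile rises roughly like the window radius below the true scale and
falls above it. The land-cover latent fields are deliberately fine-grained
(correlation length 0.5 cells, elevation weight 0.2) so that focal
fractions at neighbouring radii decorrelate; the temperature (optimum
15 °C, width 12) and ruggedness (optimum 90 m, width 600) responses are
weaker secondary drivers. Scenario generation shifts temperature-family
layers additively, scales precipitation-family layers, and converts a
seeded fraction of forest to cropland preferentially at low elevation —
mimicking cultivation pressure moving upslope and producing the
low-altitude habitat loss the change maps should detect.

What the generator does **not** emulate: real bioclimatic variable
formulas, real scenario narratives or climate-model spreads, observation
bias in presence records (roads, effort), spatial sampling autocorrelation
beyond what clustering in suitable habitat induces, and any real
geography. Passing tests therefore demonstrate that the machinery is
correct and that the inferential chain recovers known structure under its
own assumptions — not that those assumptions hold for any particular real
data set.

## Numerical choices

* Focal windows are **circular** (centre-to-centre Euclidean distance ≤
  radius), truncated at grid borders, with nodata excluded from numerator
  and denominator. Window sums use FFT convolution with a binary disc
  kernel; cell *counts* are rounded back to exact integers so focal
  fractions are exact, and focal means match a direct enumeration oracle
  to 1e-10.
* Radius-to-cells conversion is radius·1000/cell_size with no rounding of
  the distance test; a positive radius below half a cell warns and is
  treated as 0.
* Thinning keeps one record per cell, newest year first, then input
  order. The occurrence filter applies polygon → elevation → land cover,
  recording the first failing rule; the elevation interval is widened by
  the 100 m buffer on both ends, bounds inclusive.
* Aspect of flat cells is 0 with northness forced to 0, avoiding undefined
  trigonometry; topographic layers mask the outermost ring (incomplete
  neighbourhoods).
* All randomness flows from a single seed through a deterministic
  sub-seed fan-out per stage; stochastic learners are seeded and
  single-threaded, so a pipeline run is bit-reproducible from its
  configuration.

## Problem sizes

The package's own validation runs at desk scale, chosen once: 64 × 64
grids of 1-km cells, 150 presences, pseudo-absence sets of 500–2000 points
(the published workflow's 20,000 would exceed a 4096-cell toy grid), and
reduced cross-validation designs (one pseudo-absence set, one repeat)
inside the test suite, with the full 5 × 3 × 3 × 5 enumeration available
through `run_config()`.

## Known limitations

* Only convex range polygons are handled exactly in overlap computations
  (minimum convex polygons are convex by construction; arbitrary
  concave IUCN-style polygons are supported for point-in-polygon and
  buffering but not for polygon–polygon intersection).
* Raster exchange uses the plain-text ASCII grid format; there is no
  GeoTIFF reader/writer and no coordinate reprojection — inputs must
  arrive on a common metric grid.
* No spatial-block cross-validation: folds are random, as in the workflow
  this package operationalises, which can flatter evaluation metrics when
  records are spatially clustered.
* Variable importance is a permutation-decorrelation measure on the
  ensemble's predictions; it quantifies reliance, not causal
  contribution, and correlated predictors share credit.
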