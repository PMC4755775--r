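---
title: "Mapping invasion susceptibility with prediction-convergence ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping invasion susceptibility with prediction-convergence ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Forecasting where a species could invade is a correlative exercise: relate
occurrence records to environmental layers, score every grid cell's
suitability, and ask which cells outside the native range resemble occupied
habitat. Two well-known difficulties make naive habitat models unreliable for
invasion risk. First, true absences are unknown, so pseudo-absences must be
manufactured, and how they are placed shapes every downstream estimate.
Second, a model can discriminate presences from pseudo-absences around the
native range very well while failing completely to extrapolate — typically
because it keyed on incidental regional signatures rather than on the
species' climatic requirements.

`suscept` implements a framework that addresses both issues for a species
with a documented invasion: spatially constrained pseudo-absence
construction, a multi-algorithm model battery, a three-stage selection
procedure validated against *independently observed invaded locations*, and
committee-style ensembles whose agreement structure is read out as a classed
susceptibility map.

## Pseudo-absence construction

Two complementary pseudo-absence datasets are built:

* **Non-target records (BOPA-style).** Survey locations where related,
  equally detectable species were recorded but the focal species was not.
  These carry real information ("someone looked here"), provided they are
  not simply within the focal species' daily displacement range of a true
  presence. Records closer than `exclusion_radius` (default 10 km, the
  longest recorded worker-bee foraging displacement rounded up) to any
  native presence are discarded; distance `>=` the radius is kept.
* **Constrained random points.** Random locations inside the layer extent,
  outside a restriction zone (the union of `exclusion_radius` buffers around
  native presences and retained non-target records — never around invasive
  records, which are reserved for validation), outside masked cells, and
  pairwise at least `min_spacing` apart (default 15 km, which also caps
  density at about one point per 10-km cell).

The total random count follows the counting rule
`multiplier * n_native * k - k * n_bopa` so that, after the non-target
records are appended to each of the `k` random subsets, every subset holds
exactly `multiplier` (default 10) pseudo-absences per native presence.

Distances are haversine on geographic grids and Euclidean on planar
(synthetic) grids; both boundary conventions are strict-exclusion
(`d >= radius` retained). Random points are proposed uniformly over
analyzable cells with within-cell jitter and accepted by rejection sampling
against a bucket grid (budget `1000 * n` proposals); cell-uniform rather
than area-uniform proposals ignore the slight latitude distortion of
equal-angle grids at the 5-arc-minute scale.

## The model battery

The design is fully factorial: every algorithm × presence-partition run
(default 5 random 75/25 splits) × pseudo-absence subset (default 5) yields
one model, e.g. 10 × 5 × 5 = 250. Learners are pluggable: any function
mapping a labelled feature table to scores in [0, 1] can be registered.
Six families ship with the package — quadratic-polynomial logistic GLM,
smooth additive GAM (`mgcv`), boosted trees (`xgboost`), a lasso-penalized
quadratic logistic model in the maxent mould (`glmnet`), random forest
(`ranger`), and a rectangular surface-range envelope. Algorithm internals
are deliberately interchangeable; the framework's claims concern selection
and ensembling, not any single learner.

Each continuous map is binarized at the threshold maximizing sensitivity +
specificity on held-out evaluation data (the 25% presence holdout plus the
same fraction of the model's own pseudo-absence subset). Candidate
thresholds are the unique evaluation scores plus midpoints between
consecutive ones; ties resolve to the smallest candidate, which yields the
most inclusive (largest) suitable area among equally good cutpoints.

## Three-stage selection

1. **Skill near the native range.** Keep models with True Skill Statistic
   (sensitivity + specificity − 1) at or above `tss_min` (default 0.8, a
   deliberately conservative cut).
2. **Transferability.** Compute each survivor's Invasive Hit Rate — the
   fraction of invaded-range presence cells falling on predicted-suitable
   cells — and keep models at or above the survivor mean. Invasive records
   are never used in fitting; a contamination check makes this a hard error.
   This is the stage that removes high-skill, non-transferable models.
3. **Prediction convergence.** Score each survivor by the mean of pairwise
   Pearson correlations between its binary map and every other survivor's
   (the phi coefficient, computed over analyzable cells). Sweep an ascending
   threshold grid (0.50–1.00 in steps of 0.01, 51 values), retaining at each
   value the models at or above it, and build each retained set's Overall
   Prediction Model (OPM) — the binary union of members. Because the
   per-model score is fixed once after stage 2, retained sets and OPM
   suitable areas are exactly nested along the grid, and the hit rates and
   suitable-cells ratio are monotone non-increasing.

All cuts are inclusive (`>=`). Correlations on *binary* maps are the
default because the ensemble combines binary predictions and the agreement
of suitability/unsuitability calls is what convergence means here;
`pcc_on = "continuous"` is available for sensitivity analysis.

## Choosing the ensemble thresholds

In its original, manual formulation this selection was done by visual
inspection of the evaluation indices plotted against the convergence
threshold, picking thresholds
"just before marked shifts", emphasizing the Invasive Hit Rate, and
avoiding the end of the range. `suscept` codifies this: on the IHR delta
series, a shift is a negative delta exceeding `shift_c` (default 3) times
the median absolute delta — or any strict decrease when the background is
flat — or the start of a run of at least `shift_r` (default 3) consecutive
decreases; the selected threshold is the one immediately preceding the
shift, with outliers inside a decrease run resolving to the run's start and
the final threshold never selected. A manual override list reproduces any
hand-picked selection exactly, and a median-threshold fallback covers
featureless series. The constants are conventions, exposed in
`selection_config()`; no quantitative definition of "marked" exists in the
source procedure.

The selected OPMs, ordered by threshold, are summed cell-wise into the
susceptibility map. With `K` nested OPMs the classes are concentric:
class 0 is "Very Low Susceptibility or Insusceptible", class 1
"Susceptible", the top class "Susceptible at Maximum", and with `K = 3` the
single intermediate class is "Highly Susceptible". Per-algorithm agreement
maps across stages support algorithm-level diagnosis.

## The synthetic world

`synthetic_world()` builds a fully known test bed: 100 × 100 planar cells,
six unit-variance Gaussian-random-field layers (FFT-smoothed white noise,
autocorrelation scale 5 cells — small relative to the extent, as real
topoclimatic layers are relative to a global grid), one layer pair at
correlation 0.9 so collinearity pruning (threshold 0.75) always has work.
The virtual species responds to each layer with an independent Gaussian;
three strong axes (breadths 0.6–0.65 SD) plus deliberately weak responses
(breadth 2 SD) on the remaining layers, so that no layer is pure regional
noise a learner could exploit without penalty. True suitability is the
rescaled product of responses; the true range is suitability ≥ 0.5 and
occupies roughly 5–10% of the landscape, the order of magnitude real global
suitability maps produce.

The native region is a wide southern band (a thoroughly sampled
continental-scale range); the invaded region is a disjoint north-eastern
window whose environment is constructed as an *analog* of a randomly placed
native-band patch (copied values plus smooth noise, SD 0.2). This encodes
the framework's core premise — the invaded region offers conditions the
native range realizes — as a property of the generator. Without it, random
fields regularly produce invaded pockets with no native analog, and the
validation would measure the premise rather than the method. Presences are
drawn from true-range cells with probability proportional to suitability
(at fishnet grain, occupied marginal cells are expected); 2% of records are
false presences placed uniformly in the window, emulating the residual
error rate of cleaned occurrence databases. Non-target records are drawn
uniformly over the native window, suitable and unsuitable cells alike.

At this scale the real study's pseudo-absence constants are geometrically
infeasible (10 presences-worth of pseudo-absences per subset with 15-km
spacing would exceed the packing capacity of a 10,000-cell world), so the
synthetic study conditions use multiplier 5, spacing 0.75 cell units and a
1.5-cell exclusion radius — the same 10-km-cell geometry scaled to keep the
total pseudo-absence count near 30% of the free area's packing capacity.
The default battery is four learner families (GLM, GAM, boosted trees,
maxent-like) over 5 runs × 3 pseudo-absence subsets = 60 models.

What the synthetic world does **not** emulate: spatial sampling bias and
spatially autocorrelated detection error, non-equilibrium occupancy and
dispersal limitation, niche shift during invasion, interactions between
predictors, and real coastline/water masks. Passing the recovery checks
therefore shows the pipeline recovers a conserved niche under honest
conditions — not that any real invasion forecast is correct.

## Numerical choices and degenerate inputs

* Cell membership is half-open; points on shared edges belong to the cell
  right/below, so nothing is counted twice.
* Constant layers make Pearson correlation undefined and are rejected by
  name; constant prediction maps are likewise rejected in the convergence
  score with the offending model index.
* All-equal evaluation scores degrade the threshold search to that single
  value with a warning.
* Pseudo-absence generation fails loudly (reporting the achieved count)
  when constraints exhaust the rejection budget rather than silently
  under-delivering.
* One global seed fans out additively to stage-specific sub-seeds, so any
  stage can be replayed in isolation; generation and partitioning are
  bit-reproducible for a fixed seed.

## Problem sizes used by the test suite

The acceptance checks fit the default synthetic study (60 models on 10,000
cells) once and reuse it; unit tests run on 5×5 to 60×60 worlds with
two-learner batteries. These sizes were chosen as the smallest at which
every qualitative phenomenon of the full-scale study (collinearity
pruning, stage-2 removal of non-transferable learners, nested OPMs,
shift-based threshold selection) is reproducibly visible.

## Known limitations

* The framework is correlative; it does not model spread dynamics or
  evolution, and its output is susceptibility, not probability of invasion.
* The shift heuristic's constants (`shift_c`, `shift_r`) are conventions;
  different values select different OPM sets. The manual override exists
  precisely so a published hand selection can be reproduced.
* Geographic support is limited to co-registered equal-angle grids read
  from ESRI ASCII files; reprojection and resampling are out of scope.
* Area reporting uses the cell area at the equator for geographic grids.
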