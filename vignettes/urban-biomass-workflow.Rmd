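---
title: "Urban above-ground biomass from multi-scale LiDAR: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Urban above-ground biomass from multi-scale LiDAR: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(urbancanopy)
```

## The estimation problem

Urban forests store substantial above-ground biomass (AGB), but urban
trees defy the allometries built for natural stands: pollarding, street
canyons, open park growth and closed woodland produce crowns whose area
at a given height varies by an order of magnitude. `urbancanopy`
implements a workflow that couples two LiDAR scales to address this:

1. **Terrestrial laser scanning (TLS)** gives centimetre-resolution
   point clouds of a few hundred reference trees, from which
   quantitative structure models (QSMs) estimate woody volume $V$
   non-destructively. These trees anchor a *local* volume allometry.
2. **Airborne laser scanning (ALS)** covers the whole municipality at
   low pulse density (~2 pulses m^-2^). Individual tree detection (ITD)
   segments the ALS cloud into crowns, each measured for maximum height
   $H$ and projected crown area $Ar$ (2D convex hull of the crown's
   points, with equivalent radius $r = \sqrt{Ar/\pi}$).

The TLS-derived allometry then attributes every ALS crown with a volume,
wood density converts volume to AGB (and carbon via the standard 0.471
fraction), and a Monte Carlo layer propagates the three dominant error
sources. $H$ and $Ar$ are the only predictors because both instruments
can measure them; stem diameter, the classical allometric predictor,
is invisible from the air.

## Individual tree detection

The ITD is a two-stage clustering of the filtered point cloud.

**Filtering.** Points whose emitting pulse produced a single return are
dropped first — hard surfaces (roofs, roads) typically backscatter one
return, vegetation several — then points at $z \le 1$ m (ground and low
clutter). Both filters are pointwise, so their order is immaterial.

**Stage 1 — density clustering.** DBSCAN in 3D with
`eps = 3.5` m and `min_samples = 20` groups returns into crowns and
merged canopies and discards sparse clutter (building edges, aerials) as
noise. The neighbourhood radius reflects the data resolution: at
~2 points m^-2^ a 3.5 m ball (~38 m^2^ footprint) is the smallest
feature reliably supported. Points are indexed on an `eps`-sized grid,
so neighbourhood queries touch only adjacent cells. One contract detail:
when border points are claimed by an adjacent cluster (a standard DBSCAN
tie), a cluster can end up smaller than `min_samples`; such fragments
are dissolved into noise so that every reported cluster honours the
minimum-membership contract.

**Stage 2 — allometric splitting.** DBSCAN deliberately merges touching
crowns into canopies. A cluster is flagged as a merged canopy when its
radius exceeds the 95% upper prediction bound of the TLS-fitted
height-to-radius regression:

$$\beta_{95} + \alpha_{95} H < r \quad\text{(strict; equality does not split)}$$

Flagged clusters are re-clustered in the horizontal plane under a radius
threshold $B_t = \beta + \alpha H$ given by the *mean* regression line —
the expected single-crown radius at that height. The split runs as a
loop: subclusters are re-measured, any subcluster still violating the
bound is split again with its own recomputed $B_t$, and the loop stops
when no subcluster violates the bound (or after `max_iterations = 20`
rounds, in which case remaining clusters carry a `warn_nonconverged`
flag). Subclusters below `min_subcluster_points = 5` are discarded as
noise. Splitting is horizontal-only by design: $B_t$ is a crown radius,
a horizontal extent, and each subcluster's $H$ is recomputed from its
own member points.

The threshold clustering itself follows a two-run protocol. Run 1
determines the cluster count from the radius threshold alone: the count
$k$ grows from 1 until a $k$-partition (deterministic farthest-point
seeding plus Lloyd iterations) satisfies the radius bound — equivalent
radius from the subcluster's hull area — for every piece. Run 2 keeps
the count fixed at run 1's result and polishes the assignment. This
reading was chosen over two alternatives that fail structurally:

* an *RMS-radius absorption rule* (the classical cluster-feature
  radius) cannot separate two touching equal crowns, because the RMS
  radius of the union ($\approx \sqrt{r^2/2 + d^2/4}$) stays below
  $B_t$ whenever $B_t$ is calibrated to the *geometric* crown radius;
* a *greedy centroid-merge* rule can fuse fragments across two crowns,
  because a cross-tree union of two thin boundary fragments is often
  more compact than the union of two fragments of one crown.

The smallest-$k$ search directly expresses what the threshold means: a
canopy of $m$ expected-radius crowns first satisfies the bound at
$k = m$. Its known limitation — inherited from the method itself — is
that it carves canopies into similar-sized pieces regardless of the
true size mix, so uneven-aged closed canopies are segmented poorly.

**Cleaning.** Crowns with hull area below 10 m^2^ are removed (they
tend to coincide with building edges), as are crowns taller than
`max_crown_height = 45` m (cranes, aerials). Duplicates are removed by
two complementary geometric tests: hull intersection-over-union at or
above `duplicate_iou = 0.9` (two detections of the same footprint), and
*containment* — intersection over the smaller hull's area at or above
`duplicate_containment = 0.75`. The containment rule exists because the
typical duplicate is a vertically offset lower slice of a large crown:
its small hull sits inside the main hull, so the IoU of the pair is far
below any sensible IoU cutoff (~0.2 in practice) and an IoU test alone
can never remove it. The crown with more member points survives; ties
go to the taller crown.

## Allometry

**QSM quality control.** Reference trees enter the allometry only if
(i) every evaluated 1 m height slice of the TLS cloud has a mean
4-nearest-neighbour distance of at most 5 cm (the uppermost slice is
excluded — tree tops are intrinsically sparse; slices with fewer than 5
points are skipped), and (ii) the t-based 95% confidence half-width of
the 10 stochastic QSM reconstruction volumes is at most 10% of their
mean.

**Volume model.** Volume is modelled through the origin as

$$V = k_{Ar}\,Ar + k_{exp}\,(a\,b^{H}),$$

a linear crown-area term plus an exponential height term. The
through-origin constraint prevents negative predictions for small
trees; consequently the reported $r^2$ uses the *uncentred* total sum
of squares. Two fitting routes are provided:

* `method = "two_stage"` (default): fit $a b^H$ against $V$ alone,
  then regress $V$ on $Ar$ and the fitted exponential (OLS through the
  origin). This mirrors conventional practice where the exponential
  height curve is explored first. Its coefficients are *descriptive*:
  because the stage-one exponential also absorbs whatever part of $V$
  is explained by $Ar$'s correlation with $H$, and because $k_{exp}$
  and $a$ enter only through their product, the individual coefficients
  do not converge to a generating law's values.
* `method = "joint"`: co-estimate $k_{Ar}$, $a$, $b$ by nonlinear least
  squares with $k_{exp}$ fixed at 1 (the product $k_{exp} a$ is the
  identified quantity, folded into $a$). On noiseless data of this
  exact form the joint route recovers all coefficients to machine
  precision; it is the route to use when the coefficients themselves
  matter.

`weighting = "relative"` applies iteratively reweighted least squares
with weights $1/\hat{V}^2$. QSM reconstruction scatter and allometric
residuals grow roughly in proportion to tree size (the fitted residuals
are visibly heteroskedastic), so relative weighting is the
likelihood-consistent choice for multiplicative errors; under 10%
multiplicative noise it roughly quarters the error of $k_{Ar}$ relative
to OLS. The unweighted fit remains the default for comparability with
plain multiple regression.

**Threshold models.** Both ITD threshold lines come from the same OLS
regression of $r$ on $H$ over the reference trees. The mean line is
used directly as the $B_t$ model. The split trigger is the upper bound
of the two-sided 95% prediction interval (≈ mean + 1.96 residual sd for
large $n$) — using a prediction bound rather than the mean avoids
splitting legitimately large crowns; the exact bound is slightly curved
in $H$, so a straight line is re-fitted through the bound evaluated at
the training heights, keeping the deployed criterion linear.

## Uncertainty propagation

Three error sources are propagated by Monte Carlo (default 100 runs):

* **Crown measurement ("als")** — each crown's points are repeatedly
  subsampled (100 iterations retaining 75% of points) and $H$, $Ar$
  recomputed; the standard deviations parameterise per-crown Gaussian
  measurement PDFs, truncated at zero during propagation.
* **Volume ("qsm")** — Gaussian noise on predicted volume, with sd per
  crown (e.g. from the QSM reconstruction spread or the allometry's
  residual sd).
* **Wood density ("density")** — draws with replacement from the
  empirical distribution of per-tree mapped densities; no parametric
  form is imposed. One density is drawn per crown per simulation.

Freezing components isolates their contributions: the variance
decomposition runs the Monte Carlo once per component with the others
held at their point values and reports each component's share of the
summed single-component variances (shares add to one; the interaction
remainder — all-active variance minus the sum — is attached as an
attribute). With every component frozen the pipeline reproduces the
deterministic estimate exactly, which is tested bit-for-bit.

## Mapping

Volumes convert to AGB as $V \rho / 1000$ (Mg) and to carbon by the
0.471 fraction. Crowns are assigned to grid cells by hull centroid;
with the default 100 m cell, cell sums are directly Mg ha^-1^ and
trees ha^-1^. Centroid assignment (rather than area-weighted splitting)
keeps the cell totals exactly mass-conserving, which the tests assert
to 1e-9 relative. Per-cell uncertainty aggregates crown sds in
quadrature, consistent with the Monte Carlo's independence assumption
between crowns. Rasters are written as plain-text Esri ASCII grids and
crown polygons as GeoJSON.

## The synthetic scene generator

All validation runs on synthetic scenes with known truth. The generator
emulates the aspects of an urban ALS capture that the workflow is
sensitive to:

* tree crowns as parametric ellipsoids (or cones) sampled at the pulse
  density on the upper envelope (first returns) and inside the crown
  volume (second returns) — the apex is hit only with probability zero,
  reproducing the familiar slight underestimate of $H$;
* vegetation pulses yield multiple returns, building roofs single
  returns except for a small `edge_noise_prob` fraction (hard-surface
  edge artefacts), ground returns sit at $z \approx 0$;
* heights uniform over 5–35 m; crown radius follows
  $r = 0.5 + 0.25 H + \mathcal{N}(0, 0.75)$; volume follows
  $V = 0.04\,Ar + 0.05 \cdot 1.2^{H}$ with 10% multiplicative
  (lognormal) noise; 10 QSM reconstruction volumes per tree at 5%
  coefficient of variation (a t-based 95% CI of ~3.6% of volume,
  leaf-off-quality TLS). These values were fixed once as a plausible
  urban population spanning street trees to mature park trees (crown
  areas up to several hundred m^2^, volumes up to ~35 m^3^) and are
  labelled synthetic throughout.

What the generator does **not** emulate: crown asymmetry and
inter-penetration, understorey and suppressed trees, leaf-on/leaf-off
phenology, scan-angle and occlusion geometry, waveform effects, and
spatially correlated measurement error. Passing the synthetic suites
therefore demonstrates algorithmic correctness under the stated
geometry, not performance on any particular real archive.

"Well-separated" test scenes place stems with pairwise spacing of at
least $\max(12\,\mathrm{m},\, r_i + r_j + 2\,\mathrm{eps})$: the
fixed floor alone would not prevent the largest crowns of the 5–35 m
population from becoming density-connected, and the recovery criterion
presupposes geometrically separated crowns.

## Problem sizes and numerical choices

The bundled validation uses desk-scale sizes chosen as representative
rather than exhaustive: 99-tree reference populations (matching the
reference-tree count the workflow is designed around), 10 scenes of 50
separated trees (~500 detection decisions), 100-instance clustering
oracles at up to 500 points, and 1000-run Monte Carlo checks where a
CV must be resolved to a few percent. Degenerate hulls (fewer than
three distinct or collinear points) return area 0 rather than erroring
so the minimum-area cleaning rule handles them uniformly; negative
predicted volumes are clipped to zero with a count attached; duplicate
ties are broken by point count then height; all stochastic components
(generator, subsampling, Monte Carlo) restore the caller's RNG state
and are reproducible from explicit seeds.

Known limitations: crowns overlapping in reality are split along
Voronoi-like boundaries, biasing individual areas (though not their
sum) when overlap is heavy; the ITD censors trees whose true crown area
is near or below the 10 m^2^ cleaning threshold — in the synthetic
population a few percent of trees, concentrated at heights under ~7 m —
which is the dominant cause of per-scene recall dipping toward 0.9;
and compressed LAZ archives must be decompressed externally before
reading.
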