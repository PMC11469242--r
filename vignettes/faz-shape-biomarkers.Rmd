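---
title: "Inner-ellipse shape biomarkers for the foveal avascular zone"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inner-ellipse shape biomarkers for the foveal avascular zone}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fazmetrics)
```

## The measurement problem

The foveal avascular zone (FAZ) is the capillary-free region at the center of
the macula, visible as a single dark island on en face OCT angiography of the
superficial capillary plexus. In healthy eyes it is round and compact; under
systemic microvascular damage, capillary dropout erodes the surrounding
network so the avascular zone grows *outward* in irregular lobes. The working
hypothesis of this package is geometric: the healthy, pre-dropout FAZ can be
approximated by the **largest ellipse inscribable in the segmented FAZ
boundary** (the *inner ellipse*, iE), and the discrepancy between the observed
boundary and that ellipse quantifies accumulated dropout.

`fazmetrics` computes nine biomarkers from one segmented FAZ polygon:

* six established descriptors — area $A$, circularity $4\pi A/P^2$,
  acircularity $P / 2\sqrt{\pi A}$, roundness $4A/(\pi L_{\mathrm{major}}^2)$
  (with $L_{\mathrm{major}}$ the major axis of the second-moment equivalent
  ellipse), solidity $A/A_{\mathrm{hull}}$, and convexity
  $P_{\mathrm{hull}}/P$;
* three inner-ellipse biomarkers — the absolute area difference
  $\mathrm{diff\,iE} = |A - \pi a b|$, and the Hausdorff and Chamfer
  distances between the resampled FAZ and iE boundaries.

All quantities are computed on the micrometer-scaled polygon; the raster
scale defaults to $6000/1024 \approx 5.859$ µm/px, the only scale consistent
with a 6 × 6 mm en face grid in which 2.5 px correspond to roughly 14.65 µm.
The en face raster resolution is not a universal constant, so the scale is a
per-image configuration field rather than a hard-coded assumption.

## Ingestion and the polygon substrate

Segmentations enter either as binary masks (PNG/TIFF) or as QuPath GeoJSON
polygon annotations. Masks are converted with `mask_to_polygon()`: the 0.5
iso-contour of the padded binary raster is extracted by marching squares,
the largest closed contour wins (which simultaneously selects the largest
connected component and discards interior holes — the FAZ is by definition
one avascular region), and the contour is lightly smoothed with a 5-vertex
circular moving average. The smoothing step matters: on binary input the
iso-contour still chamfers in half-pixel steps, and without it the perimeter
of a smooth shape is inflated by about 6%, which would corrupt every
perimeter-based descriptor. With it, raster and vector encodings of the same
shape agree to better than 1% on all ratio metrics (this is asserted in the
test suite). Coordinates follow the image convention: x right, y down,
origin at the raster top-left, pixel centers at integer + 0.5.

```{r ingestion}
s <- generate_shape(n_notches = 3, notch_depth_um = 50, seed = 2,
                    raster = TRUE)
p <- mask_to_polygon(s$mask)
classic_metrics(p)
```

A note on the convexity convention: convexity is sometimes written as FAZ
perimeter over hull perimeter, which is $\ge 1$ and *increases* with
irregularity. The package reports hull/FAZ by default, so that convex shapes
score 1 and irregular shapes score below 1, in line with the universal
shape-analysis convention and with the direction of every other descriptor;
`convexity_convention = "ratio_faz_over_hull"` restores the reciprocal, and
the choice is recorded in the output CSV header.

## Fitting the inner ellipse

`fit_inner_ellipse()` maximises the ellipse area $\pi a b$ subject to two
constraints: every sampled ellipse-boundary point lies inside the polygon
(within `tol_um`, default 0.5 µm), and the polygon centroid lies strictly
inside the ellipse. The second constraint encodes the geometric assumption
that the center of the FAZ belongs to the healthy core; when the centroid
falls outside the polygon (an extremely concave segmentation) the fit refuses
to run unless the caller opts into the pole-of-inaccessibility fallback —
silent relocation would change the meaning of the biomarker.

Numerical design, in the order it mattered during development:

* **Parameterisation.** $(c_x, c_y, \log a, \log b, \theta)$, with the
  center offsets and log-axes expressed in units of the equal-area radius
  $\sqrt{A/\pi}$. Log-axes make positivity unconstrained; the dimensionless
  scaling is essential because Nelder–Mead builds its initial simplex from
  the parameter magnitudes, and raw micrometer coordinates (∼3000) produce
  a degenerate simplex that converges far from the optimum.
* **Containment penalty.** 256 ellipse-boundary samples by default; outside
  points are penalised by their squared distance to the polygon boundary in
  units of `tol_um`. Far-infeasible iterates subsample to 64 points for
  speed.
* **Multistart and polish.** The deterministic start is the second-moment
  equivalent ellipse shrunk by one half, plus `n_restarts − 1` seeded
  jittered starts. The incumbent is then re-solved with a fresh simplex
  until improvement stops, and finally basin-hopped with four small seeded
  perturbations. The basin-hopping stage exists because near-circular shapes
  with noisy boundaries occasionally strand the fit in a wrong-orientation
  basin that neither the multistart nor the plain re-polish escapes.
* **Repair and verification.** The candidate is shrunk radially (bisection
  on a common axis factor) until the violation, measured on 2048 boundary
  samples, is at most `tol_um`; the reported `containment_violation_um` is
  always the dense-sample value, so the invariant `violation ≤ tol` holds by
  construction rather than by optimizer luck.
* **Tie-breaking.** Among candidates whose areas agree within $10^{-6}$
  relative, the one whose center is nearest the polygon centroid wins, which
  makes the result reproducible for a given seed.

On exactly elliptical test shapes the fit recovers the generating ellipse to
about 0.1% in area; on random star-convex polygons it matches or exceeds a
brute-force grid search over center × axes × angle (both checks run in the
test suite, the grid search at 20 polygons). Area maximisation is the
natural reading of "largest" ellipse; no other size functional is supported.

```{r fit}
fit <- fit_inner_ellipse(p, seed = 1)
fit$ellipse
c(diff_ie = diff_inner_ellipse(p, fit),
  violation = fit$containment_violation_um)
```

## Boundary distances

Both boundaries are resampled to `n_points` (default 512) positions at
uniform arc-length spacing, starting at the point nearest angle zero from
the centroid so the sampling is deterministic. The Hausdorff distance is the
larger of the two directed maximum–minimum distances (µm); the Chamfer
distance averages squared nearest-point distances (µm²). The Chamfer
reduction over the two directions is configurable
(`mean_of_directions` default, `sum_of_directions`, `forward_only`) because
point-cloud implementations differ in whether they sum or average the two
directed terms; the three variants are monotone-equivalent, and the default
keeps the value on the scale of a single direction. Distances are reported
in physical units even though pixel-unit conventions exist elsewhere,
because only physical units transfer across devices.

```{r distances}
faz_ie_distances(p, fit)[c("hd_um", "cd_um2")]
```

## The synthetic FAZ family

No patient images ship with the package, so `generate_shape()` provides the
ground-truth family every numerical claim is tested on: a base ellipse
(defaults 350 × 280 µm semi-axes, a typical healthy FAZ area of ≈0.31 mm²)
plus `n_notches` outward radial bumps with a raised-cosine profile, plus
optional smooth outward boundary noise. The construction is outward-only —
capillary dropout enlarges the avascular zone — so the base ellipse is
always contained in the generated polygon, the true inscribed ellipse is at
least the base ellipse, and the bump excess area is available analytically
(by quadrature of the polar area integral) for bookkeeping tests. The
raised-cosine profile is a choice of convenience; any smooth unimodal bump
would serve.

What the generator does *not* emulate: OCT-A speckle, projection artifacts,
segmentation-threshold variability, and inward boundary defects. Passing
tests on this family therefore demonstrate that the measurement chain
responds correctly to controlled dropout-like geometry — not that the
biomarkers separate real patients.

`generate_cohort()` extends the family to a study population: per patient a
Gensini score (GS) drawn from a zero-inflated Poisson (default
`p_zero = 0.34`, `gs_mean = 35`, matching the CAD-free fraction and diseased
severity scale of a typical angiography cohort), covariates (age, sex,
diabetes) with mild severity gradients, and per eye a shape whose notch
count and depth grow monotonically with GS through `default_effect_map()`
(1 notch per 12 GS points capped at 8; depth 10 µm + 0.8 µm/GS capped at
110 µm). The left eye carries the full effect and the right eye a 0.6×
damped one, mirroring the stronger left-sided retinal involvement expected
from the carotid branching anatomy. The real effect sizes linking GS to FAZ
irregularity are unknown; these defaults are order-of-magnitude choices,
fixed once, and exposed as configuration rather than claims.

## Gensini scoring and severity groups

`gensini_score()` sums severity points (1/2/4/8/16/32 for stenosis
categories 25/50/75/90/99/100%) times coronary-segment multipliers; both
tables ship as editable JSON, and the ramus intermedius — an
anatomical-variant branch missing from the classic table — carries
multiplier 1. Stenosis percentages between categories snap to the nearest
category with a warning. `severity_groups()` maps GS to the ternary grouping
0: GS ∈ [0, 3], 1: GS ∈ (3, 31], 2: GS > 31 (the boundary "4 to 31" is read
as (3, 31] so the three groups are exhaustive for real-valued scores, with
integer GS the practical case) and to the binary grouping 0: GS ∈ [0, 3],
1: GS > 14, in which the sclerosis band (3, 14] is excluded (`NA`) rather
than labelled. Scores are kept real-valued.

## Cohort statistics

`group_difference_tests()` follows the conventional gated pathway:
Shapiro–Wilk per group and Levene's test decide between one-way ANOVA with
Tukey's HSD and Kruskal–Wallis with Dunn's post hoc test under Holm
correction (Dunn's z-tests, with tie correction, are implemented in the
package); a Bonferroni factor across metrics is applied on top. The gate
level is 0.05 by default.

`fit_zip()` fits the zero-inflated Poisson model of GS — a structural-zero
logistic part and a Poisson count part, each with the FAZ metric plus age,
sex and diabetes — by maximum likelihood (via TMB). GS is rounded to an
integer count for the outcome. Degenerate outcomes (no zeros, or only
zeros) fall back to a plain Poisson GLM with a warning instead of failing.
Parameter recovery is verified by simulation: across 200 replicates at
n = 1000, every coefficient's ±2 SE interval covers its true value in at
least 90% of fits (the test asserts per-coefficient coverage; joint coverage
of ten intervals would fail for a perfectly correct fit, since
$0.95^{10} \approx 0.60$).

`predict_cv()` evaluates severity prediction from age, sex and one
interchangeable FAZ metric with stratified five-fold cross-validation.
SMOTE (implemented in the package: k = 5 nearest-neighbour interpolation
within the minority class) is applied to the *training fold only*; the
returned `fold_detail` exposes test indices and synthetic-row counts so the
no-leakage property is structurally assertable, and the test suite asserts
it. The binary task uses logistic regression and ROC AUC; the ternary task
uses ordinal logistic regression and the unweighted (macro) mean of the
three one-vs-rest AUCs. The ordinal model defaults to the cumulative-logit
(proportional odds) form; an `adjacent_threshold` variant — separate
logistic fits between adjacent severity stages, composed into class
probabilities — is available as the configurable alternative, and also
serves as the automatic fallback when perfectly separated training data
leave the proportional-odds optimiser without valid starting values. The
95% interval on the AUC is a t-interval over the five fold estimates; fold
dispersion is the only interval source available without distributional
assumptions on so few folds.

`intergrader()` and `bland_altman()` cover agreement analysis: Dice and
Jaccard on rasterised regions (with the identity
$\mathrm{Dice} = 2J/(1+J)$ asserted in tests) and bias ± 1.96 SD limits of
agreement for paired metric values.

## Problem sizes and tolerances used in the checks

The test suite and `scripts/acceptance.R` run entirely on synthetic inputs,
sized for a single CPU: the grid-search ellipse oracle uses 20 random star
polygons of 48 vertices; the monotone-response sweep uses notch depths
0–100 µm across 50 seeds (12 in the script) with reduced fit effort
(2 restarts, 128 containment samples) justified by the near-star-convexity
of the family; ZIP recovery uses 200 replicates (60 in the script) at
n = 1000; prediction calibration uses 20 permutation-null cohorts of
n = 300. Identity tolerances are discretisation-driven: a 720-gon ellipse
is "exact" to ∼0.1%, so diff iE ≤ 2% of area, HD ≤ 2 boundary spacings and
CD ≤ one squared spacing are comfortable but not vacuous bounds.

## Known limitations

* The inner-ellipse fit is a local optimiser with restarts, not a certified
  global optimum; the oracle test bounds the gap at ≤2% on star-convex
  shapes, but pathological concave segmentations may fit worse. The fit
  refuses polygons whose centroid lies outside them unless the fallback is
  requested.
* `mask_to_polygon()` assumes one FAZ per image; multiple large components
  are resolved by size, with a warning, never by merging.
* The Chamfer and Hausdorff values depend mildly on `n_points`; 512 keeps
  the discretisation error below 5% on smooth shapes (asserted), and the
  resampling start rule makes values reproducible.
* The synthetic cohort is a device for validating machinery, not a claim
  about effect sizes in any patient population; clinical AUCs obtained on
  it have no external meaning.
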