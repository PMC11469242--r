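# fazmetrics

Shape biomarkers for the foveal avascular zone (FAZ) on en face OCT
angiography, built around the idea of the **inner ellipse**: the largest
ellipse inscribable in a segmented FAZ boundary, serving as a proxy for the
healthy, pre-dropout FAZ. Capillary dropout from systemic microvascular
disease enlarges and distorts the FAZ outward, so the discrepancy between
the observed boundary and its inner ellipse measures accumulated damage.

The package is aimed at retinal image-analysis groups studying the FAZ as a
systemic biomarker (e.g. for coronary artery disease severity), and at
anyone who needs reproducible FAZ morphometry from mask or QuPath
annotations.

For one FAZ polygon it computes nine biomarkers:

| biomarker | definition |
|---|---|
| area | shoelace area *A* (µm²) |
| circularity | 4π·A / P² |
| acircularity | P / 2√(πA) |
| roundness | 4A / (π·L²) with L the equivalent-ellipse major axis |
| solidity | A / hull area |
| convexity | hull perimeter / P |
| diff iE | \|A − π·a·b\| for the fitted inner ellipse (µm²) |
| HD | Hausdorff distance between FAZ and iE boundaries (µm) |
| CD | Chamfer distance: mean squared nearest-point distance (µm²) |

The inner ellipse is fitted by seeded constrained optimization (area
maximisation with boundary-containment and centroid-inside constraints;
multistart Nelder–Mead with polish and basin-hopping, plus a shrink repair
so the containment violation never exceeds `tol_um`).

Around the metrics sit the supporting stages of a full severity study:
mask/GeoJSON ingestion at the 6 mm / 1024 px scale (5.859 µm/px), a
synthetic FAZ and cohort generator with analytic ground truth, adjusted
Gensini scoring with ternary/binary severity groups, gated group-difference
testing, zero-inflated Poisson effect models, SMOTE-balanced binary and
ordinal logistic prediction under stratified five-fold CV, and intergrader
agreement (Dice, Jaccard, Bland–Altman).

## Worked example

Generate a synthetic FAZ with three capillary-dropout lobes (depth 50 µm),
rasterise it, and run the full measurement chain on the mask:

```r
library(fazmetrics)

s   <- generate_shape(n_notches = 3, notch_depth_um = 50, seed = 2, raster = TRUE)
p   <- mask_to_polygon(s$mask)
p
#> <faz_polygon> 476 vertices, area 325109.8 um^2, perimeter 2116.2 um

round(classic_metrics(p), 4)
#>   area_um2 perimeter_um circularity acircularity roundness solidity convexity
#> 1 325109.8      2116.15      0.9123        1.047    0.8183   0.9819     0.991

fit <- fit_inner_ellipse(p, seed = 1)
fit$ellipse
#> <faz_ellipse> center (2997.8, 2998.9) um, semi-axes 345.5 x 278.1 um, theta 3.110 rad

faz_ie_distances(p, fit)[c("hd_um", "cd_um2")]
#> $hd_um   53.13
#> $cd_um2  343.87

diff_inner_ellipse(p, fit)
#> 23257.3
```

Reading: the FAZ covers 0.325 mm² but its inner ellipse only 0.302 mm², so
about 23,300 µm² of avascular area lies outside the elliptical core — the
three dropout lobes. The largest boundary excursion (HD) is 53 µm; the
average squared excursion (CD) is 344 µm². A healthy, notch-free shape from
the same generator gives diff iE below 2% of the area and CD of a few µm².

Severity grouping from Gensini scores follows the published cut-offs
(ternary 0–3 / 4–31 / >31; binary 0–3 vs >14 with the sclerosis band
excluded):

```r
severity_groups(c(0, 23, 59))
#>   gs ternary binary
#> 1  0       0      0
#> 2 23       1      1
#> 3 59       2      1
```

A command-line front end over the same functions lives in
`inst/cli/fazmetrics.R` (subcommands `compute`, `simulate`, `gensini`,
`compare-graders`, `associate`).

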