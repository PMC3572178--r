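---
title: "Dasymetric population mapping with popweave: model, methods, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dasymetric population mapping with popweave}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popweave)
```

## The problem

Census agencies report population as totals over administrative polygons —
provinces, districts, communes, villages. Many applications (disease-burden
estimation, disaster response, accessibility modelling) instead need people
located on a regular fine grid, typically around 100 m cells. Turning polygon
totals into a gridded surface is an areal-interpolation problem, and the
simplest answer — spread each unit's count uniformly over its cells, the
areal-weighting rule used by Gridded Population of the World (GPW)-style
products — ignores everything we know about where people actually live.

`popweave` implements a dasymetric alternative in the style of the
AsiaPop/AfriPop/WorldPop family: ancillary land-cover and climate-zone data
supply per-cell density weights, and each unit's count is shared out over its
cells in proportion to those weights. The package also reimplements two
baselines (GPW-style areal weighting and a GRUMP-style urban-concentration
rule), supports urban/rural growth projection and national-total adjustment,
and ships the aggregation-based accuracy-assessment protocol used to compare
such methods, together with a seeded synthetic-landscape generator so that
everything is testable without external downloads.

## The model

Index grid cells by $i$, administrative units by $j$, land-cover classes by
$c$ and climate zones by $z$. Let $T_j$ be unit $j$'s census count and
$n_{j,c}$ the number of cells of class $c$ inside unit $j$ (computed
pixel-by-pixel by `zonal_tabulate()`). The dasymetric model assigns

$$\mathrm{pop}_i \;=\; T_j \,\frac{w_{z(i),\,c(i)}}{\sum_{k \in j} w_{z(k),\,c(k)}},$$

where $w_{z,c} \ge 0$ is the expected population density (persons per cell)
of land-cover class $c$ in climate zone $z$. Dividing by the within-unit
weight sum makes the method *pycnophylactic*: cells of unit $j$ always sum
back to $T_j$ exactly, whatever the weights. Climate-zone stratification lets
the same land-cover class carry different densities in, say, equatorial and
arid zones.

### Weight estimation

The weights are estimated from one or more countries with fine-scale census
data. For each climate zone $z$, the package solves

$$T_j \;\approx\; \sum_c w_{z,c}\, n_{j,c}, \qquad w_{z,c} \ge 0,$$

by nonnegative least squares over the units assigned to zone $z$. This is the
simplest estimator that is consistent with a pixel-level density
interpretation and directly yields the persons-per-cell weights the
redistribution step needs; nonnegativity is a physical constraint, not a
regularisation choice. Several design points were genuinely open and are
fixed as follows:

* **Unit-to-zone assignment.** A unit trains the zone containing the majority
  of its cells (ties go to the smaller zone code). Splitting cross-zone units
  would complicate the design matrix for little benefit at the unit sizes
  involved; the choice is recorded per zone in the fit diagnostics
  (`glance()`).
* **Numerical conditioning.** Class cell counts and census totals differ by
  orders of magnitude, which can stall active-set NNLS solvers. The design
  matrix is column-normalised before solving (the solution rescales exactly);
  if the active-set solver still fails to converge, a box-constrained
  quasi-Newton minimiser of the same objective takes over. Both routes return
  the identical solution on well-posed systems.
* **Underdetermined zones.** A zone with fewer informative units than classes
  is still solved (NNLS picks a nonnegative solution) but flagged
  `underdetermined` in the diagnostics rather than dropped — conservation at
  prediction time does not depend on identifiability.
* **Multi-country combination.** `combine_weights()` takes the unweighted
  arithmetic mean of each $(z, c)$ weight over the tables where it appears;
  pairs seen by a single country pass through unchanged.
* **Prediction-time fallback.** A $(z, c)$ pair never seen in training falls
  back to the across-zone mean weight of class $c$, then to zero. A unit
  whose total weight is zero is spread uniformly instead of losing its
  population (the degenerate-unit rule, logged on the output raster).
* **Urban weights.** The urban settlement class is estimated like any other
  class; no hand-set multiplier is applied.

### Baselines

*Areal weighting (GPW-style):* every cell of unit $j$ receives $T_j / n_j$.
*Urban concentration (GRUMP-style):* a share $s$ of $T_j$ is spread uniformly
over the unit's urban-extent cells and $1 - s$ over the rest; units not
intersecting the extent are areal-weighted. The original GRUMP construction
allocates per-settlement totals from an ancillary population database that
has no counterpart here, so the single configurable `urban_share` (default
0.5, per-unit overrides supported) is a deliberate simplification — it
reproduces the qualitative behaviour (population piled into urban
footprints), not CIESIN's exact algorithm.

### Growth projection and adjustment

Counts referenced to a census year $y_d$ are projected to a target year with
the compound-growth form $P = P_d (1 + r)^t$, $t = y_{\mathrm{target}} - y_d$,
where $r$ is the national urban or rural average annual growth rate chosen by
the unit's urban flag. A unit is urban if at least one of its cells coincides
with the urban extent, otherwise rural. Because each unit is scaled by a
constant, projection commutes with redistribution (tested cell-wise).
`adjust_to_national_total()` rescales a surface linearly to match an external
national estimate; being linear, it gives the same result applied before or
after gridding, so the package applies it after.

## Land-cover preparation

Source land-cover products arrive in producer-specific codes with cloud and
shadow voids and no urban/rural split. The preparation chain is:

1. **Reclassification** to a fixed nine-class model legend (two reserved
   settlement classes, `URBAN` = 8 and `RURAL_SETTLEMENT` = 9; the seven
   remaining labels are configurable). Unmapped source codes are a hard
   error, never silently dropped.
2. **Void filling**: every nodata cell takes the class of its nearest
   non-void cell by Euclidean distance between cell centers, with a
   deterministic tie-break (smallest row, then column index). The operation
   is idempotent and never alters non-void cells; the implementation applies
   donor offsets in globally sorted distance order, which the test suite
   checks against an exhaustive nearest-donor scan.
3. **Settlement refinement**: binary built/residential masks are fused by
   logical OR with the settlement classes, and an urban-extent overlay
   splits built cells into `URBAN` (inside) versus `RURAL_SETTLEMENT`
   (outside). The refinement never shrinks the built area.

## Grid and vector conventions

All rasters in one model run must share an identical `grid_spec`; this is
asserted before every pixel-wise operation. The grid origin is the outer
corner of cell (0, 0), cells are half-open squares, and cell area is treated
as constant (planar approximation) — adequate for the regional extents the
method targets; latitude-dependent cell-area weighting is out of scope.
Polygons are rasterized by the cell-center rule, with centers on shared
boundaries assigned to the lexicographically smallest `unit_id` so that
rasterization is byte-for-byte deterministic. Rasters are exchanged as
plain-text ESRI ASCII grids and admin units as GeoJSON; a reserved integer
sentinel marks nodata and is never a valid class code.

## Accuracy assessment

The protocol mirrors how gridded-population methods are validated when a
finer reference exists: sum the fine-level census up to the coarser level
(`aggregate_units()`), rebuild the surface from the coarse counts only, then
compare each fine unit's observed count with the sum of modelled cells inside
it. Reported per method: RMSE, %RMSE ($100 \cdot \mathrm{RMSE} /
\overline{\mathrm{obs}}$), MAE, and Pearson's $r$ (with $r^2$ alongside,
since published correlation tables are sometimes ambiguous between the two;
$r$ is reported as undefined, not 0, when estimates are constant). Method
error distributions are compared with the tie-corrected Kruskal-Wallis test
on per-unit absolute errors, followed by the Siegel–Castellan
critical-difference procedure on mean ranks at a configurable familywise
$\alpha$ (default 0.05). Per-unit signed errors can be painted back onto the
grid (`error_raster()`) for under/over-estimation maps, and observed-versus-
estimated scatter data are exported for plotting.

## The synthetic generator

`synthetic_scenario()` fixes every input of a reproducible study: a patch
mosaic land cover (each cell takes the class of its nearest seeded patch
center — a deterministic, platform-independent construction chosen over
stateful region-growing queues because it is pure, vectorisable and gives the
same patchy class mixture), horizontal climate bands, disk-shaped urban
blobs, nested rectangular admin units, optional uniformly injected voids, and
a census generated from known ground-truth weights, either exactly
(`noise_model = "none"`) or as seeded Poisson draws. Default densities follow
the ordering real products estimate — near zero on water, sparse on natural
cover, moderate on cropland, one to two orders of magnitude higher on
settlement classes (150 persons/cell urban, 30 rural settlement, at roughly
1 ha cells) — with a per-zone multiplier so stratification matters.

What the generator does *not* emulate: spatially autocorrelated census error,
misaligned boundaries, digitising slivers, realistic urban morphology or
landscape geostatistics. Passing tests therefore demonstrate correctness of
the estimator and redistribution machinery under known truth, not performance
on real national data.

## Problem sizes and numerical tolerances

The test suite exercises mass conservation on 256×256 grids with 64 fine
units, weight recovery on 48×48 grids (exact to ≤1e-6 relative on noiseless
full-rank designs; median relative error ≤5% under Poisson noise at unit
totals ≥10⁴ across 20 seeds), and the method comparison on twenty seeded
40×40 scenarios, where the dasymetric method is expected to achieve the
lowest RMSE in at least 18 of 20. Conservation is asserted to 1e-9 relative,
reduction identities (constant weights ≡ areal; per-unit urban share equal to
the urban cell fraction ≡ areal) to 1e-12. These sizes keep a full run in
tens of seconds while leaving every design full-rank.

## Known limitations

* National growth rates only; sub-national urban/rural rate variation is not
  modelled.
* The GRUMP-style baseline is parameterised, not a faithful reconstruction.
* Constant cell area; no reprojection or resampling — inputs must already
  share a grid, and users preparing real 30 m land cover for a coarser model
  grid must choose their own resampling rule upstream.
* Weight estimation assumes density is a function of (zone, class) only; no
  covariates such as roads, slope or night lights, and no regression-tree
  refinement.
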