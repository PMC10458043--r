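---
title: "Methods: presence-only maximum entropy and land-cover change"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: presence-only maximum entropy and land-cover change}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecosuit)
```

## Scope and model

`ecosuit` couples two analyses that conservation studies of
narrow-range species typically run together: a presence-only
species-distribution model (SDM) that maps habitat suitability from
occurrence points and environmental rasters, and a multitemporal
land-use/land-cover (LULC) change analysis over categorical map epochs.

### The maximum-entropy model

Given presence records $x_1,\dots,x_m$ and a background sample of $n$
cells drawn uniformly from the landscape, the model seeks the
distribution over the background that is as close to uniform as possible
(maximum entropy) while matching the empirical means of a set of
environmental *features* at the presences.  Equivalently, it maximizes
the L1-regularized training gain

$$G(\lambda) \;=\; \frac{1}{m}\sum_{i}\lambda^\top f(x_i)
  \;-\; \log \sum_{j \in \text{bg}} e^{\lambda^\top f(x_j)}
  \;+\; \log n \;-\; \sum_k \beta_k |\lambda_k|,$$

so $G(0) = 0$ and $G$ measures log-likelihood improvement over the
uniform model.  Fitting is cyclic coordinate descent (one soft-threshold
Newton step per feature, with backtracking so the gain never decreases),
stopping when a full cycle improves $G$ by less than the convergence
threshold ($10^{-5}$ by default) or after `max_iterations` (2000)
cycles.

Features are built from the variables: linear, quadratic, pairwise
products, forward/reverse hinges and step functions on 50 evenly spaced
interior knots per variable, and one indicator per categorical level.
Continuous variables are min/max-normalized over presence + background,
so every feature lies in $[0, 1]$.  Which classes are used follows the
emulated software's presence-count rule (linear always; quadratic from
10; hinge from 15; product and threshold from 80 presences).

The raw output $r(x) = e^{\lambda^\top f(x)}/Z$ sums to one over the
background.  With $H$ the entropy of that fitted distribution, the
cloglog output $1 - \exp(-e^{H} r(x))$ and the logistic output
$\tau e^H r / (1 - \tau + \tau e^H r)$ (prevalence $\tau = 0.5$) rescale
it to an interpretable 0–1 suitability.  With total shrinkage
($\beta \to \infty$) every cell's cloglog value is exactly
$1 - e^{-1}$, a closed form the tests use.

### Regularization defaults

$\beta_k$ is the regularization multiplier (default 1) times the
published per-feature-class default, interpolated by presence count $m$:
linear/quadratic/product go from 1.0 at small $m$ to 0.05 at
$m \ge 100$; categorical 0.65 to 0.25; threshold 2.0 to 1.0; hinge is
0.5 throughout.  The emulated software additionally scales these by the
feature's presence-sample standard deviation over $\sqrt m$; because our
features are already normalized to $[0,1]$ we apply the table values
directly — a deliberate simplification that keeps $\beta$ on the
documented scale.  An explicit `beta` argument overrides the table
entirely (the unit tests use it to pin down 1-D optimizer oracles).

### Variable importance

*Percent contribution* credits every coordinate-descent gain increment
to the updated feature's source variable, floors negatives at zero and
normalizes to 100.  *Permutation importance* permutes one variable
jointly across presence + background rows (one seeded permutation by
default; replicates configurable), recomputes training AUC with frozen
weights, floors the drop at zero and normalizes to 100.  The *jackknife*
refits with each variable alone and with each variable omitted; by the
nesting of feature sets, neither gain can exceed the full-model gain.
AUC is rank-based (Mann–Whitney with half-credit ties), so it equals
exhaustive pair counting.  Only training AUC is computed: the emulated
workflow describes no held-out split, and the package flags this rather
than inventing one.

### Thresholding and classification

The binary presence/absence map uses the *q*-th percentile training
presence rule (default $q = 10$) with the nearest-rank definition —
the threshold is an attained prediction value, and at most $q$% of
training presences fall strictly below it.  Cells exactly at the
threshold count as presence.  The five-class suitability table uses
fixed-width bins $[0,0.2), [0.2,0.4), [0.4,0.6), [0.6,0.8), [0.8,1]$;
binning is implemented with `findInterval` because `floor(v/0.2)`
misclassifies exact bin edges in binary floating point (0.6/0.2 is
2.999…96).  The present-vs-future change report prints both absolute
presence shares and the relative change
$100(A_\text{future}-A_\text{current})/A_\text{current}$, because a bare
"expansion of X%" is ambiguous between the two readings.

## Grid conventions and I/O

Rasters live on a shared `grid_spec` (upper-left origin, square cells in
metres, opaque CRS tag).  Alignment is validated everywhere;
reprojection is out of scope.  A point maps to the cell
`floor((origin_y - y)/cell)`, `floor((x - origin_x)/cell)` (half-open
cells).  Continuous downscaling uses bilinear interpolation, categorical
resampling nearest/majority, DEM upscaling block means; any window that
touches nodata yields nodata, so missingness can only grow, never leak
into valid cells.  Slope (in percent, as summary tables in this field
print it) and aspect come from Horn's 3×3 weighted differences; aspect
is the downslope azimuth clockwise from north, and flat cells get
*nodata* aspect rather than a sentinel like −1, which would pollute
circular statistics.

Raster I/O uses the plain-text ESRI ASCII grid with a `.prj` sidecar
carrying the CRS tag (read fails without one, by design).  No
GeoTIFF-capable R package is available in the supported environment;
the ASCII grid preserves values bit-exactly (17 significant digits) and
keeps every artifact inspectable as text.

## Occurrences, thinning, collinearity

Thinning keeps at most one record per grid cell — the *first* in input
order, a deterministic tie-break the source workflow leaves unspecified
— and is idempotent.  Multiple occurrence sources can be pooled before
thinning (the package pools; whether the original fieldwork datasets
were pooled is not documented).  The occurrence area is the convex hull
of the (thinned) points, with shoelace area, exported as WKT.

Collinearity pruning computes pairwise Pearson correlations over
jointly valid cells, links variables with $|r| \ge$ cutoff (default
0.8), takes connected components (single linkage, so within-group
linkage may be transitive), and keeps one representative per group.
The emulated tool picks a random representative; the default here is
the lexicographically first name for reproducibility, with a seeded
random mode available.  Categorical layers never enter the matrix and
are always retained.  Zero-variance layers have undefined correlations;
they are reported and treated as uncorrelated.

## LULC change analysis

Epoch maps are categorical rasters on the common grid with a
hierarchical legend (`code`, `level1`, `level4`); analyses can run at
level 1, level 4, or a mixed scheme supplied as an explicit
code-to-class mapping (the occurrence-area scheme in the motivating
workflow mixes 4 coarse and 10 detailed classes).  Mask membership is a
cell-center point-in-polygon test (deterministic, unlike GIS polygon
overlay with partial cells).  Class-area tables are percentages of valid
masked cells; transition matrices are cross-tabulations whose row/column
sums reproduce the per-epoch tables exactly, with persistence the
diagonal share.  `table_change` also accepts typed-in published
percentage tables so printed deltas are reproducible without any raster
(the package ships the two published tables it was validated against;
one printed delta in their source text, +5.7 for one oak class,
disagrees with its own table cells, which give +5.6 — the package
reports table values and does not reconcile prose).

## The synthetic world

The generators replace proprietary rasters and undeposited occurrence
records.  What they emulate, and the defaults:

* **Environment** — independent Gaussian white-noise fields smoothed
  with a separable Gaussian kernel (`smooth_sigma = 5` cells, so fields
  have realistic spatial autocorrelation and thinning is non-trivial),
  z-scored and mixed through the Cholesky factor of a target correlation
  matrix.  Default grid 200×200 at 100 m — the analysis resolution of
  the motivating study at desk scale.  The default correlation is
  identity except $r = 0.9$ between `V1` and `V2`, so the default world
  contains exactly one collinear pair for the pruning step to resolve.
  A categorical soil field (quantile bins of an extra smooth field) and
  a DEM accompany the climate-like fields.
* **True suitability** — a linear + quadratic score on z-scored
  variables pushed through the same raw → cloglog chain the model uses.
  Defaults: a strong monotone driver (`V1`, weight 4), a secondary
  unimodal driver (`V4`, 1.5 linear, −0.75 quadratic, niche peak one SD
  above the mean) and a weak driver (`V6`, 0.75).  This yields map-wide
  mean suitability below 1% — a narrow endemic, matching the motivating
  system, where the species occupies a small fraction of the study area
  and the reported model discriminates strongly (training AUC ≈ 0.9).
  A weaker, flatter surface would describe a generalist and would not
  support the recovery properties the tests assert; that choice of world
  was made once, on this reasoning, and the acceptance thresholds were
  not adjusted to it.
* **Occurrences** — `m = 200` cells drawn with probability proportional
  to true suitability (without replacement by default), one point per
  cell center.
* **LULC** — epoch 1 is quantile-binned from a smooth field (spatially
  coherent patches at the prior proportions); each later epoch evolves
  every cell independently through a per-pixel Markov kernel (default
  0.9 persistence).  Empirical transition frequencies recover the kernel
  within binomial error.

What the generators do *not* emulate: real climatology or geography
(values are z-scores, not degrees or millimetres), observation bias in
occurrence records, vector-map rasterization artefacts, and spatially
correlated LULC transitions (cells evolve independently).  A green
recovery test therefore establishes that the estimator works on a
well-specified world of the right shape — not that it reproduces any
particular real-data number.

## Numerical choices and edge cases

* Coordinate updates skip features whose background variance is below
  $10^{-12}$; steps are capped at 5 and halved until the gain does not
  decrease, so the gain path is monotone by construction.
* Background sampling is uniform without replacement over valid cells;
  presence cells are eligible.  Fewer valid cells than requested uses
  all of them with a warning.
* Ties in `block_mode` resampling resolve to the smallest class code.
* The global pipeline seed fans out per stage via a polynomial string
  hash modulo $2^{31}-1$, so stages are independently reproducible and
  derived seeds stay within R's integer range.
* Degenerate inputs error loudly: grids under 3×3 for terrain
  derivatives, fewer than 3 distinct or collinear points for hulls,
  empty masks, unknown legend codes (listed), missing model layers
  (named), out-of-range thresholds and suitability values.

## Known limitations

* Training-only evaluation: no cross-validation or held-out AUC.
* The correlation-pruning representative rule (lexicographic) can keep
  a different variable than a random-choice tool would; groups are
  otherwise identical.
* Hinge/threshold knots sit on an even grid (50 per variable) rather
  than at every data value; very fine response-curve structure can be
  smoothed out.
* No CRS reprojection, vector rasterization, clamping/extrapolation
  diagnostics, bias grids, or cumulative output.
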