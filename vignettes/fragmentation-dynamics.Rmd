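---
title: "Methods: quantifying forest fragmentation dynamics with fragdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying forest fragmentation dynamics with fragdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fragdyn)
library(dplyr)
```

## The model

`fragdyn` treats every square analysis cell of a gridded study extent as
an independent landscape. Within a cell, the binary forest lattice is
summarized by three class-level metrics that capture the three classic
faces of fragmentation: edge density `ED = e/A × 10,000` (m/ha, the edge
effect), patch density `PD = n/A × 10,000 × 100` (patches per 100 ha,
the isolation effect) and mean patch area `MPA` (ha, the patch-size
effect), together with forest coverage `FC`. The composite forest
fragmentation index is the weighted mean of the normalized metrics with
MPA inverted,

$$\mathrm{FFI} = w_{ED}\,ED' + w_{PD}\,PD' + w_{MPA}\,(1 - MPA'),$$

so that 0 reads "single intact block" and 1 reads "maximally edge-rich,
patchy, small-patch landscape". Change is simply the difference between
two epochs: $\Delta\mathrm{FFI} = \mathrm{FFI}_2 - \mathrm{FFI}_1$, and
likewise $\Delta FC$. The index is descriptive, not mechanistic: its
value depends on the normalization bounds and weights, which is why both
are recorded with every run.

Key assumptions: the two maps are co-registered, in a projected
equal-area CRS with square pixels (the package checks and refuses
otherwise, and never reprojects); a grid cell is a closed landscape, so
patches are truncated at cell borders; and fragmentation is meaningfully
summarized at the chosen cell grain. The grain is the user's scientific
choice — 5 km cells for global work, smaller for regional studies — and
results are not grain-invariant (no landscape metric is).

## Normalization with cross-epoch comparability

The three raw metrics live on incommensurate scales, so each is min–max
rescaled before composition. The bounds are percentiles of the *pooled*
two-epoch distribution over forest cells, and the identical bounds are
applied to both epochs. Pooling is the only choice that makes FFI values
comparable across years: with per-epoch bounds, a cell whose metrics did
not change could still change index value because its neighbours
changed. The default clip is `(0, 100)` (plain min–max); `(0.5, 99.5)`
is offered where single outlier cells (one giant patch in an otherwise
uniform region) would otherwise compress everyone else into a corner of
the unit interval. Values beyond the bounds are clamped into `[0, 1]`.
Bounds are fitted with the standard linear-interpolation sample
quantile, and a metric that is constant over forest cells is a hard
error rather than a silent divide-by-zero — such an input means either a
degenerate study area or a bug upstream.

The weights default to equal thirds: the three metrics proxy three
distinct effects with no a-priori ranking, and equal weighting keeps the
index interpretable as "average abnormality". They are exposed for
sensitivity analysis.

## Conventions that needed deciding

Several small conventions materially affect the numbers and are fixed,
documented defaults here:

* **Connectivity** defaults to 8 (queen's case), matching the common
  default of class-level landscape metric engines; 4 is available.
* **Window borders are not edge** (`count_boundary = FALSE`): a fully
  forested cell should read ED = 0, i.e. unfragmented, rather than
  acquiring a perimeter artefact.
* **Nodata** pixels count as neither forest nor edge partner (an
  unobserved boundary is not a real boundary), the landscape area `A`
  stays the nominal cell area so density denominators remain comparable,
  and a cell more than half nodata is dropped entirely (configurable).
* **Partial boundary cells** are excluded by default because `A` would
  differ from `cell_size²`; they can be kept, flagged, with their true
  area used.
* **Ties in sign classification**: "up" means strictly positive change;
  an exact zero classifies as "down". This keeps the 8 modes and 4
  patterns total and exhaustive. Exact zeros have measure zero on real
  data; for exactness-sensitive work `tie = "exclude"` returns `NA`
  instead. A descriptive "stable" flag (`|ΔFFI| < 0.005` by default)
  is reported without adding a ninth/fifth class.
* **Cell windows** are stored as 1-based inclusive pixel ranges — the
  idiomatic R convention — with cell ids assigned row-major from the
  top-left; the windows are disjoint and tile the extent exactly, which
  is what matters for reproducibility.
* **Cell size must divide evenly into pixels.** Real 30 m data with a
  5000 m target grain should be snapped (e.g. 5010 m cells, or resampled
  pixels) before analysis; the package refuses to build ragged windows
  because per-cell resampling would make `A` ambiguous.

## Driver attribution

The driver model is ordinary least squares — a general linear model with
identity link and Gaussian errors — of ΔFFI on seven covariates
(mean/change of cropland coverage, nighttime light and population
density, plus fire frequency), with response and covariates min–max
rescaled to `[0, 1]` so coefficients are comparable across factors. The
rescaling is computed on the fitted rows (after incomplete rows are
dropped), never on rows that do not enter the fit. Confidence intervals
use the conventional multipliers ±1.645 SE (90%) and ±1.960 SE (95%);
p-values are two-sided from the t distribution with no multiplicity
correction, since coefficients are read jointly from one model per
region. Exact collinearity is a hard error naming the offending columns;
near-collinearity is the user's modelling problem, deliberately not
"fixed" silently. The coarse-grid major-driver map refits the model per
block (≥ 30 rows by default; smaller blocks and failed fits yield
nodata) and reports the covariate with the largest absolute coefficient.

## What the synthetic generator emulates — and what it does not

The generator produces spatially autocorrelated binary maps by the
modified-random-clusters recipe: seed pixels at density
`p × (1 − autocorr)`, then neighbour-accretion growth until the realized
proportion hits the target (always within ±0.01 of `p`, by
construction). One knob controls autocorrelation; higher values give
fewer, larger patches at equal cover. The second epoch is produced by
canonical change operators — edge erosion, dissection, perforation,
attrition, infill, seeding, expansion — each with an intensity in
`[0, 1]` and an optional region, applied in schedule order. Each
application draws from its own stream derived from `(seed, step index)`,
so editing a schedule does not scramble unrelated draws. A fixed
operator-effect table records the directions each operator robustly
implies (e.g. dissection: ED+, PD+, MPA−, FC−, FFI+; infill the
mirror); directions that are not robust for a stochastic operator are
left unasserted rather than over-promised.

This emulates the *statistical* structure the pipeline cares about —
autocorrelated cover at two epochs linked by known processes, plus
smooth driver fields with planted linear effects — and nothing else. It
is not an ecological simulation: no growth, dispersal, fire spread,
topography, or calibration to real forest-cover statistics. Passing
tests therefore demonstrate that the *pipeline* recovers known
processes from data of realistic spatial character, not that any
real-world conclusion is reproduced. Real 30 m global data differ in
ways the generator does not attempt: anisotropic patch shapes,
heavy-tailed patch-size distributions, spatially structured nodata, and
drivers correlated with each other and with baseline fragmentation.

Study-condition defaults used throughout the checks: 45% initial cover
with autocorrelation 0.9 (large-patch landscapes where both
fragmentation and coalescence have room to act), 30 m pixels, 20×20-pixel
cells; the end-to-end recovery check uses a 100×100-cell scenario and
the regression calibration uses n = 5000 cells, 100 replicates for
recovery and 200 for type-I error — sizes chosen to make simulation
noise small relative to the tolerances being checked while keeping the
suite quick on one CPU.

## Numerical choices and degenerate inputs

Patch labeling is a deterministic breadth-first connected-component pass
(compiled): labels follow the row-major position of each patch's first
pixel, so identical inputs give identical labelings everywhere. Edge
counting enumerates each 4-neighbour pair once. Weights must sum to 1
within 1e-9; cell/coarse sizes must be integer multiples of their
grains within 1e-9 of a pixel. A cell with no forest gets ED = PD = 0,
`MPA = NA`, FC = 0 and is excluded from index composition (undefined
MPA) and from change classification; a cell forested in only one epoch
keeps its static FFI for that epoch but gets no ΔFFI — change rows exist
only on the epoch intersection. Empty strata, empty zones and failed
per-block regressions degrade to warnings plus empty/`NA` outputs, never
to silent numbers.

## Raster formats

Input and output rasters are plain-text Esri AAIGrid with an optional
`.prj` sidecar; a sidecar declaring a geographic (degree-unit) system is
rejected with instructions to reproject, since all metric arithmetic is
in metres. GeoTIFF is not read or written by this build — there is no
GDAL binding among the dependencies — and the reader says so explicitly
rather than guessing at pixel geometry. Normalization bounds are
serialized to YAML so that later runs can normalize new data
bit-identically; the pipeline writes a manifest of MD5 content hashes,
and identical inputs plus config reproduce the hashes exactly.

## Known limitations

* Patches are truncated at cell borders; a landscape-spanning corridor
  counts once per cell it crosses. This is the "cell = landscape"
  definition, not an approximation, but it means PD at coarse grains is
  not additive across grains.
* Min–max normalization ties the index to the observed distribution:
  FFI values from different study areas (or different clip percentiles)
  are not directly comparable. Compare only within a run, or reuse a
  serialized parameter set.
* The driver model is associational OLS with classical errors; no
  spatial autocorrelation correction is applied, so standard errors on
  strongly autocorrelated residual fields will be optimistic.
* The simulator's operators act on pixels, not on land-use processes;
  intensities are not calibrated to any real disturbance rate.
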