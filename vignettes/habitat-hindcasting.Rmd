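---
title: "Hindcasting habitat and quantifying within-population variance: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hindcasting habitat and quantifying within-population variance: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refugia)
```

## What the package models

`refugia` reconstructs where a wide-ranging tree species — the motivating
case is trembling aspen, a boreal clonal pioneer — could have persisted
through the last glacial cycle, and connects that reconstruction to the
genetic signature that post-glacial recolonisation leaves in quantitative
traits. The pipeline has two largely independent arms:

1. **Habitat arm.** Monthly climate normals are reduced to bioclimatic
   variables; a bagged classification-tree ensemble (random forest) relates
   presence/absence records to those variables; the fitted model is
   projected onto palaeoclimate surfaces built by the delta (anomaly)
   method; hindcasts are validated against fossil-type presence records by
   ROC/AUC; and the product of present-day and Last Glacial Maximum (LGM)
   probabilities of presence maps habitat stability — the chance a cell
   stayed inside the species' climatic tolerances through the cycle.
2. **Genetics arm.** A randomised complete block (RCB) provenance trial is
   analysed with an all-random linear mixed model. The residual variance
   component, estimated separately per geographic region of seed origin,
   serves as a proxy for within-population genetic variance: all
   provenances share the environment at a test site, so regional
   differences in residual variance are genetic in origin (dominance and
   epistasis included, environmental variance held constant).

Because the original census, fossil and trial data are not deposited
anywhere machine-readable, every input is emulated by a synthetic-data
module with known ground truth. That choice is deliberate: each stage can
then be tested against the generating truth rather than against a frozen
copy of somebody's output.

## Bioclimatic variables

Eleven variables are derived from 36 monthly normals (12 Tmin, 12 Tmax,
12 precipitation): `DD5`, `DD0`, `MWMT`, `MCMT`, `TD = MWMT - MCMT`
(continentality), `MAT`, `MAP`, `MSP` (April–September), `MWP`
(November–February), `PAS` and `NFFD`. The model-fitting default is the
six-variable low-collinearity subset `DD5, MWMT, TD, MAP, MSP, MWP`.

Degree-days and frost-free days need daily resolution, which normals do
not have. The package defines the daily series as the piecewise-linear
interpolation between month midpoints on a fixed 365-day calendar
(month lengths `31, 28, ...`), wrapping December to January, followed by
truncated daily summation:

$$\mathrm{DD5} = \sum_{d=1}^{365} \max(0,\; T_d - 5), \qquad
  \mathrm{DD0} = \sum_{d=1}^{365} \max(0,\; -T_d).$$

This closed definition was chosen over published regression
approximations because it is exactly reproducible and admits an
independent brute-force oracle: the test suite recomputes every
degree-day and frost-day value with a deliberately naive daily loop and
requires agreement to 1e-6. Useful exact limits follow from the
definition: a constant annual temperature $T$ gives
$\mathrm{DD5} = 365\max(0, T-5)$ and $\mathrm{DD0} = 365\max(0,-T)$, and
adding a positive constant to all months can never decrease DD5 nor
increase DD0.

Two conventions deserve a note. `TD` is defined as warmest-month minus
coldest-month mean (not fixed January/July), which is the standard
continentality measure and is what the variable-name glossary in the
field uses. `MWP` wraps November–February within the single climatological
year, since normals carry no year identity; `MWP` is in mm (a
temperature unit sometimes appears next to it in secondary sources — a
typo). `PAS` counts the precipitation of months with mean temperature at
or below 0 °C; monthly mean is the simplest defensible threshold given
that no finer rule is standard.

## Palaeoclimate overlay (delta method)

Coarse GCM-style anomalies are combined with the fine baseline as

$$T'_{m} = T_{m} + \Delta T_{m}, \qquad P'_{m} = P_{m} \times f_{m},$$

with the anomaly layers first regridded to the baseline geometry by
bilinear interpolation between cell centres. Multiplicative precipitation
factors are the standard delta-method choice because they preserve
non-negativity; an additive mode clamped at zero exists behind
`precip_mode = "additive"` for sensitivity checks. One anomaly is applied
to both Tmin and Tmax, as no min/max split is available from coarse
anomalies. In the half-cell margin outside the outermost coarse centres
the bilinear stencil extrapolates linearly rather than clamping, so
planar anomaly fields are reproduced exactly over the whole covered
extent; nearest-cell assignment was rejected because it introduces
blocky artefacts at exactly the scale the SDM consumes. An optional 0/1
ice mask per period forces masked cells to nodata before prediction, the
mechanism by which ice-covered area is excluded from habitat.

Derived variables are computed *after* the overlay, never perturbed
directly — a linearity check in the tests confirms, e.g., that halving
all monthly precipitation halves MAP cellwise.

## Species distribution model

The SDM is a bagged ensemble of classification trees
(`randomForest`). Probability of presence is the fraction of tree votes;
out-of-bag (OOB) vote fractions are stored per training record and give
an internal AUC without a holdout. Defaults: 500 trees, no class
weighting (synthetic prevalence is controlled by the niche), balanced
per-tree sampling available via `balance = TRUE` for absence-heavy real
data. Fits are deterministic given the seed. Tree count and bagging
parameters are recorded in the model object for transparency since no
canonical values exist.

Validation against fossil-type records extracts the hindcast probability
at each record's cell, drops and counts records on nodata or ice-masked
cells, and computes AUC per period plus pooled over all periods by
concatenating (score, label) pairs — both are reported because pooling
conventions differ between studies. AUC itself is the Mann–Whitney pair
statistic with mid-rank ties, so it is invariant under strictly
increasing transforms of the scores.

## Habitat stability

The stability surface is the cellwise product of the modern and LGM
probability surfaces; it is bounded above by the smaller factor, so a
cell is only stable if it is suitable in *both* states of the climate
system. Classification thresholds for "moderate" and "high" persistence
default to (0.25, 0.5); no principled universal values exist, so they are
arguments, and the area summary reports cell counts alongside area so
the classification is auditable.

## The provenance-trial variance model

For each region and trait the model is

$$Y_{ijkl} = \mu + P_i + S_j + (P{\times}S)_{ij} + B(S)_{jk}
  + (P{\times}B(S))_{ijk} + e_{l(ijk)},$$

with every term random and Gaussian: provenance, site,
provenance-by-site, block within site, provenance-by-block (row plot),
and residual. For traits scored at a single site the site and
provenance-by-site terms drop and block-within-site becomes a simple
block effect. Estimation is REML (`lme4`), matching the convention of
mixed-model software that provenance analyses traditionally use, with
variance components constrained non-negative at the boundary.

Standard errors are asymptotic, from the inverse REML information
matrix $\mathcal{I}_{cd} = \tfrac12\,\mathrm{tr}(P G_c P G_d)$ evaluated
at the estimates, where $G_c$ is the derivative of the marginal
covariance with respect to component $c$ and $P$ is the REML projection.
This is the classical likelihood-based SE of a variance component (the
COVTEST-style output of mixed-model software). SEs are reported as `NA`
for components estimated at zero, where the asymptotic approximation
fails. Because the computation builds an $n \times n$ covariance matrix
it is intended for region-scale fits (roughly $n \le 2000$), which is
how the analysis is run; pass `se = FALSE` for bulk simulation studies.

On balanced designs REML coincides with the closed-form ANOVA
method-of-moments estimators; the tests exploit this with a one-way
balanced toy whose components are computed by hand from the
between/within mean squares. Location shifts change only $\mu$; scaling
by $c$ multiplies every component by $c^2$ — both are asserted.

## What the synthetic generator emulates — and what it does not

* **Climate** (`make_climate_grid`): a latitudinal temperature ramp, a
  July-peaking seasonal cycle, a constant diurnal range (so
  Tmax ≥ Tmin holds by construction), and an elevation-like correlated
  noise field built by smoothing seeded white noise with a Gaussian
  kernel (circular convolution, unit cellwise variance). Precipitation
  is a 12-value profile scaled by a lognormal spatial field, hence
  non-negative. Defaults (0.5 °C/row lapse, 15 °C seasonal
  half-amplitude, 8 °C diurnal range, ~2 m-per-cell-scale correlation
  length 3 cells) give a 50 × 50 grid whose DD5 spans roughly 0–2500,
  a realistic boreal-to-temperate span for niche contrast.
* **Anomalies** (`make_anomaly_grid`): period presets with mean cooling
  −1.5, −3, −5, −8 °C and precipitation ratios 0.95–0.75 for 6k, 11k,
  14k, 21k years BP — the conventional ordering of late-glacial to
  mid-Holocene anomaly magnitudes, strongest at the LGM — modulated
  seasonally (winter-amplified) and spatially.
* **Occurrences** (`sample_occurrences`): cells sampled uniformly with
  replacement (a dense plot network revisits climatically similar cells;
  sampling without replacement is available and errors cleanly when the
  grid is exhausted), labels Bernoulli at the niche probability, truth
  retained per record.
* **Fossils** (`make_fossil_records`): occupancy is thresholded truth;
  labels flip with false-positive rate (pollen blown into lake
  sediments from elsewhere) and false-negative rate (fragile pollen
  failing to preserve). Flips are exactly recoverable because the truth
  travels with the record.
* **Phenotypes** (`simulate_trial`): observations built exactly under
  the variance model above, per region, all effects independent
  mean-zero Gaussians. The default design is 43 provenances in six
  regions (7/7/7/8/7/7) × 5 sites × 6 blocks × 5-tree plots = 6,450
  height records, with the two phenology traits scored at one site
  (1,290 records). Generating residual variances follow the regional
  within-population components reported for boreal aspen provenance
  trials (`aspen_residual_components()`: height 0.61–0.94 rising from
  BC Northeast to Minnesota; bud break 8.4–13.1; senescence 5.2–10.3);
  the unreported remaining components are fixed fractions of the
  regional residual (provenance 0.3, site 0.5, provenance×site 0.1,
  block 0.05, provenance×block 0.1) — large enough that REML rarely
  hits the zero boundary, so the residual estimate stays clean.

None of this emulates real topography, GCM physics, taphonomic spatial
structure, or mortality-driven imbalance. A green test suite therefore
demonstrates that the *algorithms* are correct and that the pipeline
recovers known truth under its own assumptions — not that any particular
real-data AUC or variance estimate would be reproduced. Real
presence/absence compilations are strongly absence-heavy and spatially
clustered; the `balance` option and the drop-counting in extraction
exist for that case but are not exercised by the defaults.

## Numerical choices and degenerate inputs

* 365-day calendar everywhere; no leap years.
* Random terms with fewer than two levels, with as many levels as
  observations, or duplicating another term's partition (e.g.
  provenance×block collapsing onto provenance when there is one block)
  are dropped automatically; a design with no replication within plots
  is an error, as the residual would be confounded.
* A constant response short-circuits to all-zero components with
  `mu` equal to the constant (REML is undefined at zero total variance).
* PCA (`pca_ordination`) analyses the correlation matrix by default, so
  loadings scaled by the singular values are variable–component
  correlations (the usual biplot vectors); the sign of each component is
  fixed by making its largest-magnitude loading positive; zero-variance
  columns are an error naming the column. Provenance means (not
  tree-level records) feed the trait ordination, matching a design in
  which symbols represent provenances; under the balanced design these
  are least-squares means.
* AUC requires both classes and says so explicitly; per-period AUC is
  `NA` with the record counts still reported when a period is
  single-class after drops.

## Problem sizes used by the tests and acceptance script

The parameter-recovery studies run 100 replicate simulate-and-refit
cycles per regional trait (≈1,050 observations each, ~20 s per trait),
which puts the Monte-Carlo standard error of the mean residual estimate
near 0.5% of its value — tight enough to detect any estimator bias that
would matter at the reported precision. The end-to-end hindcast runs on
a 50 × 50 grid with 5,000 training occurrences and 2,000 fossils, 300
trees. These sizes were chosen so the full pipeline exercises every code
path at statistically meaningful resolution while staying desk-scale.

## Known limitations

* No GeoTIFF I/O: rasters are exchanged as ESRI ASCII grids, which any
  GIS reads, but metadata is limited to geometry (no CRS strings).
* The SDM contract is vote-fraction bagging; other ensemble flavours
  (gradient boosting, leaf-probability averaging) are out of scope.
* Real-data magnitudes — an OOB AUC near 0.9 on continental census
  data, fossil validation near 0.67 — depend on undeposited data and are
  not targets of this package; the synthetic analogues bound behaviour
  from above (separable niche → OOB AUC ≈ 1) and calibrate degradation
  under taphonomic noise.
* Variance-component SEs are asymptotic; for components with few levels
  (site, with 5) they are indicative at best, which is why the analysis
  reports the residual component — supported by hundreds of degrees of
  freedom — as the quantity of interest.
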