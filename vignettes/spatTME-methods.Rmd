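---
title: "spatTME: models, conventions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{spatTME: models, conventions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spatTME)
```

## What the package computes

spatTME analyzes tables of segmented cells exported by multiplexed
immunohistochemistry platforms (one row per cell: position in µm, tissue
category, per-marker mean intensity, phenotype label and confidence),
together with a per-sample geometry of the epithelium/tumor compartment.
Its stages are:

1. **Quality filter.** Cells called with a phenotype confidence of more
   than 50% are retained (`filter_by_confidence()`, strict `>`).
2. **Threshold phenotyping.** Per-marker hi/lo cutoffs are derived from the
   intensity distribution and used to partition cells into the four
   CD68/CD163 subsets (`CD68hiCD163lo`, `CD68hiCD163hi`, `CD68loCD163hi`,
   `CD68loCD163lo`) and into PD-L1/PD-1 hi/lo classes.
3. **Signed-distance profiling.** Each cell's Euclidean distance to the
   epithelium/tumor–stroma interface, negative inside the tumor
   compartment and positive in the stroma; per-subset cell densities
   (cells/mm²) are binned along this axis and aggregated across samples as
   mean ± SE.
4. **Nearest-distance and contact statistics.** Mean nearest distance
   (MND) of a subset to tumor cells, and centroid-rule contact counts of
   PD-1^hi^ T cells with PD-L1^hi^ partners.
5. **Outcome association.** Spearman screening of distance-band densities
   against outcome variables, median-split (or fixed-threshold) patient
   dichotomization, and Kaplan–Meier/log-rank comparison at selected bands
   (e.g. density of PD-L1^hi^ CD68^hi^CD163^hi^ cells at +75 µm).

A seeded synthetic-cohort generator supplies ground-truthed data for every
stage, because the tissue data behind this class of study are generally
not deposited.

## Threshold model

Marker intensities of a mixed cell population are typically bimodal on a
log scale.  `fit_marker_threshold()` therefore fits a two-component
Gaussian mixture to `log10(intensity + 1)` by EM (the offset of one
intensity unit admits zeros) and places the cutoff at the equal-posterior
crossing between the component means, back-transformed to intensity units.
"hi" is strict (`>`) everywhere, so a cell exactly at a threshold is "lo";
the special threshold 0 separates "no expression" from "any expression".

Numerical choices: EM is initialized by a median split, runs at most 500
iterations to a relative log-likelihood tolerance of 1e-10, and orders
components by mean.  The crossing is the root of the log-posterior
difference between the means; if extreme weights leave no sign change
there, a dispersion-weighted midpoint is used.  If the fitted components
are separated by less than 0.5 pooled SD the mixture is declared
degenerate and the method falls back to mean + 2 SD on the log scale; the
fallback and the mixture diagnostics are recorded in the returned fit and
in the JSON sidecar written by the pipeline.  Thresholds are fitted once
per cohort (pooled samples); per-sample fitting is possible by calling the
fitter per sample, but single cohort-wide cutoffs are the default because
a staining batch shares one intensity scale.

With well-separated components the misclassification of this rule
approaches the Bayes error of the generating mixture, which is
`pnorm(-separation/2)` for equal weights and SDs: about 6.7% at 3 SD
separation and 0.02% at the 7.5 SD separation used by the default
synthetic intensity model.  A "< 5% misclassification" expectation is
therefore only attainable for separations of roughly 3.3 SD upward — the
acceptance fixture uses the default 7.5 SD world.

## Geometry and the signed distance axis

Three geometry representations are supported: disc nests (closed-form
distances; the synthetic default), polygons (exact point-to-segment
distances, even-odd parity for the sign), and label masks (0 = outside,
1 = stroma, 2 = epithelium/tumor).  Masks are processed with an exact
Euclidean distance transform; because pixel-centre distances overestimate
the distance to the half-way interface by half a pixel, 0.5 px is
subtracted.  Mask distances are accurate to about one pixel (2 µm at the
default resolution); disc and polygon distances are exact.  A cell exactly
on the boundary has distance 0 and sorts with the tumor side (`d < 0` is
the tumor compartment, so 0 belongs to stroma bins — one consistent
half-open convention `[a, b)` is used on the whole axis).

Band areas (the denominators of the density profile) are computed by
rasterizing the geometry at 2 µm/px (configurable; an error is raised if
the resolution is coarser than a quarter bin) and tabulating the
signed-distance field.  For disc geometries whose bands neither clip the
frame nor overlap another nest's bands, exact annulus areas are used
instead; the two paths agree within the raster tolerance and are
cross-checked in the tests.  With several nests a point is assigned the
band of its *minimum* distance to any boundary — multi-nest geometries
whose bands interleave are resolved by this rule, which is a package
convention rather than an externally defined one.

**Binning.** The profile grid defaults to 25 µm bins.  The canonical
reporting bands sit at −25, +25 and +75 µm *centres*, so the default range
is ±512.5 µm: half-bin-shifted edges put every multiple of 25 µm on a bin
centre.  (A ±500 µm range with the same bin width would put the canonical
bands on bin *edges* instead; the shifted grid is the only way both
conventions coexist.)  The maximum profiling distance is a default, not a
statement about tissue.

## Nearest distances and contacts

`nearest_distance()` excludes a to-cell with the same identifier as the
query cell, so a set matched against itself gives nearest *non-self*
distances; MND is the arithmetic mean of the per-cell distances.
`count_contacts()` uses a centroid rule — contact iff the centroid
distance is at most `r_ref + r_partner + slack` (slack 1 µm) with radii
from the segmented cell area (`r = sqrt(area/pi)`, default 5 µm when
absent).  True mask-level touching detection needs segmentation masks that
tabular exports do not carry; the centroid rule is the documented
approximation and is pluggable.  Both statistics have grid-accelerated
implementations that agree *exactly* with their brute-force counterparts
(verified on every test instance up to n = 1000).

## Statistics

* **Group comparisons** use the two-sided Wilcoxon rank-sum test with
  Bonferroni correction (`p_adj = min(1, p * family_size)`).  For
  `n_a + n_b <= 12` the null distribution is enumerated over all rank
  assignments; midranks make the enumeration valid under ties (identical
  groups give p = 1 exactly).  Larger samples use the normal approximation
  with tie-corrected variance and continuity correction, which matches
  `stats::wilcox.test` on the same settings.
* **Spearman screening** correlates each patient-level band density with
  each outcome column, pairwise complete.  For n ≤ 9 the p-value is exact
  over all n! permutations; otherwise the t approximation is used.
  Constant columns are flagged, not errors.  Because follow-up is
  censored, the screen emits correlations against *both* the event
  indicator and the follow-up time; this dual encoding is a documented
  assumption, and the screen-then-KM sequence is exploratory — no
  multiplicity adjustment is propagated into the log-rank stage.
* **Survival.**  Median splits put ties at the median into the low group
  (`hi` is strictly above); the threshold-0 split separates zero from any
  positive covariate.  The Kaplan–Meier estimator uses the standard
  deaths-before-censorings tie convention and the two-group log-rank
  (Mantel–Cox) statistic is computed from the per-event-time 2×2 tables;
  both are validated against the `survival` package and hand-computed
  tables.  Patients with several samples contribute the mean of their
  samples' band densities.

## The synthetic world

The generator states one fixed world (changing it to make a test pass is
out of bounds):

* **Frame** 3 × 3 mm — the size of a multispectral imaging region — with
  disc-shaped tumor nests of radius 250–350 µm.  The default is one nest
  per sample: nests are kept one profile-range (512.5 µm) clear of the
  frame edge and of each other so band areas stay exact, and two such
  exclusion zones rarely fit a 3 mm frame.  Multi-nest worlds are
  supported with smaller ranges.
* **Spatial models.**  CD68^hi^CD163^lo^ (boundary intensity
  150 cells/mm², decay 75 µm) and CD68^hi^CD163^hi^ (120 cells/mm²,
  100 µm) accumulate at the boundary on both sides; CD68^lo^CD163^hi^
  (80 cells/mm²) and leukocytes (500 cells/mm²) are uniform in stroma;
  T cells accumulate at the boundary (400 cells/mm², 150 µm); tumor cells
  fill the nests at 1500 cells/mm².  Sampling is an inhomogeneous Poisson
  process realized by thinning, which is exact and seedable.
* **Intensities** are two-component log-normals (log10 means 1.0/2.5,
  SD 0.2 — 7.5 SD separation); checkpoint positivity decays into the
  stroma with a 100 µm scale from subset-specific maxima.  Confidence is
  Beta(8, 2) (mean 0.8, ~2% of cells below the 50% filter).
* **Survival** is exponential with baseline hazard 0.02/month and log
  hazard ratio β per SD of the patient's realized density of PD-L1^hi^
  CD68^hi^CD163^hi^ cells in the +75 µm band (default β = −0.7,
  protective).  Patients are censored independently with probability 0.3
  at a uniform fraction of their event time.  A log-normal patient-level
  abundance multiplier (SD 0.3) induces realistic between-patient density
  correlation across bands.

What the generator does *not* emulate: irregular nest shapes, segmentation
artefacts, staining gradients, spectral bleed-through, holes/folds in the
tissue, and multiple samples per patient with discordant biology.  A green
test therefore establishes correctness of the computations on an idealized
tissue, not robustness to real-world imaging artefacts.

Tests and simulations use scaled-down cohorts (fewer patients or lower
intensities than a full study) to stay within CPU budgets; the scaling is
in the test code, never in the generator defaults.

## Known limitations

* Tabular inputs only; the package deliberately does not re-implement
  spectral unmixing, tissue/cell segmentation or the platform's
  phenotyping models, and consumes their outputs.
* Geometry masks are read from plain-text integer grids (CSV) and
  polygons from GeoJSON; binary TIFF/PNG masks must be converted first.
* Contact counting is centroid-based (above), not mask-based.
* No Cox or multivariable survival modelling — only the median/threshold
  split log-rank workflow.
* The optional Ki-67 channel is carried as a marker column but enters no
  dedicated analysis.
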