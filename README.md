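# spatTME

Spatial analysis of the tumor microenvironment from multiplexed
immunohistochemistry (IHC) cell tables.

Multiplexed IHC platforms segment tissue images into single cells and
export, for every cell, its position, tissue category (epithelium/tumor
vs. stroma), per-marker mean fluorescence intensity, a phenotype call and
a call confidence.  spatTME turns those tables into the spatial statistics
used to study how myeloid and T-cell subsets arrange themselves around
tumor nests, and whether that arrangement is associated with patient
outcome.  It is written for analysts working with head-and-neck squamous
cell carcinoma (HNSCC)-style cohorts — tumor nests embedded in stroma,
CD68/CD163-defined macrophage-associated subsets, PD-L1/PD-1 checkpoint
markers — but every marker, rule and grid is configurable.

## The statistics at its core

* **Threshold phenotyping.** A two-component Gaussian mixture on
  log₁₀(intensity + 1) yields per-marker hi/lo cutoffs (equal-posterior
  crossing); cells are classified into CD68^hi^CD163^lo^,
  CD68^hi^CD163^hi^, CD68^lo^CD163^hi^, CD68^lo^CD163^lo^ and into
  PD-L1/PD-1 hi/lo, with hi ⇔ intensity > threshold.  Cells with call
  confidence ≤ 0.5 are removed first.
* **Signed distance-to-boundary profiles.** For each cell, the Euclidean
  distance *d* to the epithelium/tumor–stroma interface (*d* < 0 inside
  the tumor compartment).  Per-subset density profiles bin *d* (25 µm
  bins) and divide per-band counts by per-band tissue areas (exact
  Euclidean distance transform of the geometry), giving cells/mm² vs.
  distance, averaged across samples with standard errors.
* **Nearest-distance and contact statistics.** Mean nearest distance
  (MND) of each subset to tumor cells, and the fraction of PD-1^hi^
  T cells in centroid-rule contact (≤ r₁ + r₂ + 1 µm) with PD-L1^hi^
  partners, by partner class.
* **Distance-band survival association.** Each patient's density in a
  chosen band (e.g. +75 µm) becomes a covariate: Spearman screening
  against outcomes, median (or threshold-0) dichotomization, and a
  Kaplan–Meier / log-rank (Mantel–Cox) comparison.  Wilcoxon rank-sum
  tests with Bonferroni correction serve for group comparisons throughout.
* **Synthetic cohorts.** A fully seeded generator (disc-shaped nests,
  inhomogeneous-Poisson subsets that accumulate at the boundary or stay
  uniform in stroma, bimodal log-normal intensities, Beta confidences,
  exponential survival whose hazard depends on a band density) provides
  ground truth for every stage.

## Worked example

```r
library(spatTME)

cfg <- synthetic_config(seed = 2024, survival = list(n_patients = 12))
res <- run_pipeline(pipeline_config(synthetic = cfg, seed = 2024), "out")

res$thresholds$CD68
#> <threshold_fit> CD68: 67.43 (gmm2)

head(subset(profile_table(res$profiles$CD68hiCD163hi),
            bin_center_um >= -50 & bin_center_um <= 75))
#>    bin_center_um mean_density_mm2    se total_count n_samples
#> 19           -50             67.9 17.07          32        12
#> 20           -25             98.2 21.63          51        12
#> 21             0            100.9 12.80          57        12
#> 22            25             83.8 16.55          52        12
#> 23            50             81.8 14.60          54        12
#> 24            75             46.5  7.55          33        12

res$survival$splits[3, ]
#>                 covariate cutoff n_hi n_lo  chi2       p
#> 3 CD68hiCD163hi_PDL1hi@75      0    5    7 8.185 0.00422
```

Reading the output: the mixture threshold for CD68 landed at 67.4
intensity units; the CD68^hi^CD163^hi^ density profile peaks at the tumor
boundary (≈ 101 cells/mm² at the 0 µm bin, mean ± SE over 12 samples) and
decays into the stroma, matching the generator's boundary-accumulation
model.  Among the screened survival covariates, the density of PD-L1^hi^
CD68^hi^CD163^hi^ cells at +75 µm — exactly the band the generator's
hazard model used — separates the cohort most strongly (log-rank
χ² = 8.19, p = 0.004), with the high-density group surviving longer
(the generator's β = −0.7 is protective).

`out/` additionally contains `profiles.csv`, `mnd.csv`, `contacts.csv`,
`checkpoint_proportions.csv`, `correlation_screen.csv`,
`survival_splits.csv`, `thresholds.json`, a JSON manifest and a run log.

A command-line front end with `generate` / `analyze` / `report` verbs is
installed at `inst/cli/spattme.R`.

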