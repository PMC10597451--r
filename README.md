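# fbgeo

Geostatistics and environmental-driver analysis of the soil
fungal:bacterial (F:B) ratio.

Fungi and bacteria are the two main decomposer guilds of soil, with
distinct metabolisms: decomposition is fast and mineralizing where bacteria
dominate, slower and more carbon-retentive where fungi do. The F:B ratio —
here `100 × (18S rDNA copies per g soil) / (16S rDNA copies per g soil)`,
measured by qPCR — is used as a bioindicator of that balance across
soil-monitoring networks. fbgeo is for microbial ecologists and soil
scientists who need to turn raw multi-plate qPCR tables and site covariates
into calibrated densities, maps, and ranked environmental drivers, with
every step reproducible from a seed.

The package implements, as tidyverse-style functions over data frames:

* **qPCR master-curve calibration** — per-plate Ct drift correction against
  replicated reference DNA (`derivation = plate reference mean − global
  reference mean`), one pooled calibration line per target
  (`Ct = intercept + slope·log10(copies)`), absolute quantification, F:B
  ratios.
* **Geostatistics** — Matérn variogram models `γ(h) = c₀ + c(1 − ρ_ν(h/a))`
  fitted by profile maximum likelihood (smoothness selected over
  ν ∈ {0.5, 1.5, 2.5}), ordinary kriging with a local neighbourhood,
  leave-one-out cross-validation with standardized squared prediction
  errors `θᵢ = (zᵢ − ẑᵢ)² / σ²ₖ,ᵢ` (mean ≈ 1, median ≈ 0.455 when the model
  is right), gridded map export.
* **Response conditioning** — Shapiro–Wilk screen, profile-likelihood
  Box-Cox, iterative Grubbs outlier removal.
* **Driver analysis** — iterative VIF filtering (threshold 5), exhaustive
  BIC subset screening, forward selection under an adjusted-R² ceiling with
  Freedman–Lane permutation tests, and variance partitioning by partial RDA
  into soil / land-management / climate / spatial / jointly-explained
  fractions (Ezekiel-adjusted R² units; the decomposition closes exactly).
* **Land-use contrasts** — tie-corrected Kruskal–Wallis, Bonferroni
  rank-LSD post hoc with compact letter display, tail fractions of soils
  below/above ratio thresholds.
* **A synthetic survey generator** — a 16 × 16 km jittered systematic grid
  (default 2,171 sites), spatially autocorrelated log densities from exact
  Cholesky draws of Matérn fields, covariates with planted effect signs,
  and raw qPCR plates with planted offsets — so every stage has a
  ground-truth recovery test and nothing needs downloading.

Results come back as tibbles or classed objects with `tidy()`, `glance()`
and `autoplot()` methods.

## Worked example

```r
library(fbgeo)

cfg <- synthetic_config(n_sites = 400)        # survey-like defaults
sim <- simulate_sites(cfg, seed = 1)          # sites + ground truth
report <- run_pipeline(sim$sites, responses = "fb_ratio",
                       nu_candidates = 0.5, n_perm = 99, seed = 1)
report
```

```
fbgeo run report (n = 400 sites, seed = 1 )

== fb_ratio ==
  transform: boxcox; outliers removed: 0
  variogram: nu 0.5, effective range 141.1 km
  LOO: mean SSPE 1.001, r^2 0.029
  varpart: total adj R^2 0.267 (shared 0.115)
  land use: H = 57.02, p = 2.54e-12
```

Reading the numbers: the ratio needed a Box-Cox transform (Shapiro screen
rejected normality) and no Grubbs outliers were removed; the fitted
exponential variogram puts the practical autocorrelation range at ~141 km
on this 400-site draw (small surveys estimate the range loosely — at 2,000
sites the estimate tightens around the planted 84 km); the mean
standardized squared prediction error of 1.001 says the variogram model is
well calibrated, while the low LOO r² says short-range variability
dominates point prediction; the environmental model explains 26.7% of the
transformed ratio variance, of which 11.5 points are jointly explained by
correlated predictor groups; and land uses differ strongly (H = 57, df = 3)
— the post hoc letters separate forest (highest ratios) from crop and
grassland, with vineyards/orchards overlapping both lower classes.

Real data enter through `read_sites()` (CSV with `site_id`, projected
`x_km`/`y_km`, covariates, land-use and climate classes, and either
densities or a precomputed `fb_ratio`) and `calibrate_plates()` (long-format
well tables); coordinates must be projected to planar km first.

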