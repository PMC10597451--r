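---
title: "Mapping and explaining the soil fungal:bacterial ratio: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping and explaining the soil fungal:bacterial ratio: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fbgeo)
library(dplyr)
```

The fungal:bacterial (F:B) ratio summarises the balance between the two main
decomposer guilds of soil. fbgeo implements the full analysis chain used to
characterise this ratio across a national soil-monitoring grid: absolute
quantification of 16S and 18S rDNA copies from multi-plate qPCR data,
geostatistical mapping, and environmental driver ranking. This vignette is
the package's own account of each model, its assumptions, the tunable
parameters, and the design choices made where conventions were genuinely
open.

## 1. qPCR calibration by the master-curve method

Threshold cycles (Ct) drift between plates. Every plate therefore carries
triplicate wells of one shared reference DNA and a 10-fold plasmid dilution
ladder. Calibration proceeds in four steps:

1. the **global reference mean** Ct is computed over all reference wells of
   one target gene, pooled across plates;
2. each plate's **derivation** is its own reference mean minus the global
   mean;
3. the derivation is subtracted from every Ct on that plate (**corrected
   Ct**), after which each plate's reference mean equals the global mean to
   machine precision — an identity the tests assert;
4. a single **master curve** (OLS of corrected Ct on log10 copies) is fitted
   to the pooled standards of all plates, and each sample's copies per
   reaction is `10^((Ct - intercept)/slope)`.

16S and 18S are calibrated independently throughout: they are separate
assays with different chemistry, so reference means, derivations, and curves
never mix targets.

Two conventions deserve note. First, plate offsets are only identified up to
their common mean: the derivation of plate *p* equals the planted offset
minus the mean offset. The unidentified constant is absorbed by the master
curve intercept, so quantification is exact regardless — the noiseless
round-trip test checks relative errors below 1e-9. Second, the paper trail
from copies per reaction to **copies per gram of soil** depends on the DNA
yield and template mass conventions of the assay; fbgeo exposes this as a
single `conversion` factor (default `1e4`, i.e. a 20 µg DNA yield per g soil
divided by a 2 ng template). Absolute densities are comparable only within a
fixed conversion convention; the F:B ratio, defined as

```
fb_ratio = 100 * (18S copies per g) / (16S copies per g),
```

is invariant to it when both targets share the same convention.

Failed wells (missing Ct) propagate as missing densities and the calibration
object reports the success count. Reference replicate standard deviations
above 0.5 cycles raise a diagnostic flag but nothing is trimmed.

## 2. Geostatistics: Matérn variograms, kriging, cross-validation

Spatial structure is modelled with a constant-mean Gaussian process whose
covariance is `C(h) = c * rho_Matern(h; a, nu) + c0 * 1{h = 0}`: `c0` is the
nugget (micro-scale plus measurement variance), `c` the partial sill, `a`
the distance parameter, `nu` the smoothness. All coordinates are planar
projected kilometres; reproject longitude/latitude before entry — no module
ever sees spherical coordinates.

**Fitting** is by maximum likelihood, not least squares on the empirical
variogram (which `empirical_variogram()` provides as a diagnostic only,
with 10-km default lags and a maximum distance of one third of the
bounding-box diagonal). The mean and the overall variance are profiled out
analytically, so the optimizer (Nelder–Mead) works on only two parameters,
`log a` and `log(c0/c)`; this keeps 2,000-site fits at a handful of seconds
and makes them reproducible. The smoothness is selected over the discrete
grid `{0.5, 1.5, 2.5}` — the likelihood is notoriously flat in continuous
`nu`, and these half-integer values have closed-form correlations
(`nu = 0.5` is the exponential model `exp(-h/a)`). A fit whose partial sill
falls below 5% of the total variance is flagged as pure nugget.

The **effective range** reported everywhere is the practical 95% range: the
distance at which the semivariance reaches `c0 + 0.95 c`, found numerically
(for the exponential model this is `-log(0.05) a`, about `3a`). An observed
autocorrelation distance of ~84 km therefore corresponds to `a` ≈ 28 km at
`nu = 0.5`.

**Ordinary kriging** solves the best-linear-unbiased-prediction system on
the `neighborhood` nearest samples (default 64 — the survey-scale convention
for "local neighbourhood" kriging; weights sum to 1 by construction and the
tests assert it to 1e-10). Between distinct measurements the nugget does not
correlate, so duplicate sample locations are regularized by any positive
nugget; with a zero nugget they raise an explicit singular-system error. The
target-sample covariance at distance zero uses the full sill, so predictions
honour observed data exactly.

**Leave-one-out cross-validation** predicts every site from the others with
the fixed fitted model and reports the standardized squared prediction error
`theta_i = (z_i - zhat_i)^2 / sigma2_k,i`. Under a well-specified model
theta is approximately chi-squared with 1 df: mean near 1, median near
0.455. Inflating the sill by a factor scales every theta by its inverse
exactly — a useful misspecification diagnostic. The squared correlation of
observed and LOO-predicted values is reported as the LOO r²; map-quality
"R²" figures in survey reports are labelled as this quantity without
asserting they were defined identically.

## 3. Response conditioning

Before any model: a Shapiro–Wilk screen (valid for 3 ≤ n ≤ 5000); if
normality is rejected at 0.05, a Box-Cox transform whose λ maximizes the
profile log-likelihood over [-2, 2] (the profile criterion, rather than any
forecasting heuristic, because the goal is an approximately Gaussian
residual distribution); then iterative Grubbs outlier removal **on the
transformed scale**. The scale choice was genuinely open — detection could
precede the transform — but outliers feed models that run on transformed
values, so flagging them on that scale is the coherent reading; it is fixed
here and recorded in every run report. Grubbs is applied iteratively (a
single-outlier test must be repeated to find several), two-sided at
α = 0.05, with a default cap of 5 removals to prevent pathological stripping
of heavy-tailed samples. Ties break on the first index, so removal order is
deterministic. Applying a power transform before a rank test is redundant
(ranks are invariant, and the Kruskal–Wallis H is identical before and
after — a property the tests assert); the pipeline nevertheless applies the
stated order so that run reports document one conditioning chain for all
downstream analyses.

## 4. Environmental driver analysis

For a univariate standardized response, redundancy analysis reduces to
ordinary least squares: R² is the fraction of response variance explained,
and the partitioned currency is the Ezekiel adjustment
`1 - (1 - R²)(n - 1)/(n - p - 1)`. Quantitative predictors are standardized;
categorical predictors enter as treatment-coded 0/1 dummies whose
coefficients are reported on that scale. Sand is excluded from models — it
is the complement of clay + silt by construction.

The selection cascade mirrors standard practice:

* **VIF filter**: iteratively remove the quantitative column with the
  largest `1/(1 - R²_j)` until all VIF ≤ 5; categorical columns are exempt;
  exact duplicates are dropped first and logged.
* **Best-subset BIC screen** (exhaustive up to 20 candidates) as an optional
  second screen.
* **Forward selection** maximizing adjusted R²: a candidate enters only if
  its marginal permutation p-value (conditioned on the terms already in the
  model) is below α **and** the running adjusted R² does not exceed the
  full-model ceiling. This is the established two-criterion convention for
  constrained ordination. One documented consequence: when the true model is
  dense among the candidates, the ceiling legitimately stops selection one
  term early in roughly half of replicates (the reference implementation in
  the vegan package behaves identically on the same data); the robust
  guarantees are that terms enter in effect order and spurious columns stay
  out.
* **Permutation tests** use Freedman–Lane residual permutation of the
  reduced model, `p = (1 + #{F* >= F})/(1 + n_perm)`, seed-controlled.
  Defaults are 999 permutations in exploratory calls (raise toward 10,000
  for publication-grade p-values).

**Variance partitioning** across the predictor groups (soil, land
management, climate, spatial) uses partial RDA: the unique fraction of a
group is the full-model adjusted R² minus that of the model without the
group; the jointly explained "interactions" fraction is the total minus the
sum of unique fractions, so the decomposition closes exactly (asserted to
1e-10). Small negative unique fractions are reported as-is, never clipped.
The **spatial descriptors** are a convention the source material leaves
undefined; fbgeo uses standardized coordinates and their second-order
polynomial (x, y, x², y², xy) — a plain trend surface, flagged as such in
run reports, and results sensitive to this choice should be read
accordingly.

## 5. Land-use contrasts

The omnibus test is the tie-corrected Kruskal–Wallis H with a chi-squared
reference (the chi-squared p agrees with the exhaustive permutation null to
within ~0.06 at n = 8, which the tests document). Post hoc contrasts follow
the rank-LSD convention: differences of mean ranks against a t quantile with
pooled rank variance `S²(N - 1 - H)/(N - k)`, Bonferroni-multiplied by the
number of pairs and capped at 1. The compact letter display assigns a shared
letter to every maximal set of mutually non-significant groups; the
invariant maintained is that no two groups sharing a letter differ
significantly. `threshold_fractions()` reports per-group shares of soils
below/above fixed ratio thresholds (defaults 1 and 5, the band containing
most temperate soils).

## 6. The synthetic monitoring network

`simulate_sites()` generates data shaped like a national 16 × 16 km
systematic survey (default 2,171 sites — cell centres of a ~950-km square
grid, subset at random to emulate the irregular territory, with small
uniform jitter). The log10 F:B ratio is modelled directly:

```
log10(FB) = 0.442 + landuse_effect + X beta + mediterranean_effect
            + Matern_field + noise
```

with planted signs pH −, organic C −, C:N +, coarse elements +, silt −,
available P + (plus small Ni + and Cu − effects), land-use deviations
ordered grassland < vineyard/orchard < crop < forest, a single positive
Mediterranean climate effect, a ratio-specific Matérn field (84-km effective
range, nugget:sill 1:4, total field variance 0.01 log10²) and residual SD
0.19. The bacterial log density has its own drivers (organic C +, C:N −,
pH +, clay +) plus shared and bacterial-specific fields; the fungal density
is derived as `log10(F) = log10(B) + log10(FB) - 2`, so the ×100 ratio
identity holds exactly and the simulated F:B map has spatial structure of
its own, distinct from either density map. Covariate marginals (pH 4–8.5,
C:N 8–25, lognormal organic C, P, metals) depend on land use — forests more
acidic with higher C:N and organic C, vineyards copper-enriched — which is
what creates the jointly explained variance fraction downstream. The
intercept 0.442 puts the median simulated ratio near 2.7; effect magnitudes
were chosen once, from the variance budget, so that in expectation the soil
group uniquely explains on the order of 10% of the ratio variance and the
full model around 30% — enabling scaled recovery tests without claiming the
synthetic truth reproduces any real data set.

What the generator deliberately does **not** emulate: a coastline polygon
(the grid bounding box stands in for the territory; a mask hook exists),
mechanistic soil-carbon dynamics, realistic pedoclimate maps, within-site
sampling error of the covariates, and qPCR inhibition or melt-curve
failures. Passing recovery tests therefore demonstrate that the estimators
recover what they model — not that real soils satisfy the model.

`simulate_plates()` lays out wells exactly as the assay describes:
triplicate reference DNA and a 10-fold standards ladder (10²–10⁷ copies per
reaction, triplicate) on every plate, samples in triplicate round-robin,
`Ct = 38 - 3.3219 log10(copies) + plate_offset + N(0, 0.15)` with plate
offsets N(0, 0.5). With the default σ_Ct, error propagation across
triplicate wells and plate correction leaves ~95% of quantified densities
within ±25–30% of truth; with σ_Ct = 0 the round trip is exact.

## 7. Numerical choices and problem sizes

* Optimizer: Nelder–Mead on 2 log-parameters, reltol 1e-8, max 500
  evaluations; initialization at a quarter of the mean pairwise distance and
  a nugget:sill ratio of 0.5. Non-convergence raises an error carrying the
  optimizer state; no silent fallback.
* Cholesky factors are reused across replicate field draws; a 1e-10
  diagonal jitter (with a message) handles covariances that are PSD only up
  to rounding.
* Effective ranges are found by bisection to a relative tolerance of 1e-10.
* Seeds: every stochastic entry point takes an explicit seed and restores
  the caller's RNG state; fixed seed implies byte-identical output.
* Test and verification problem sizes are chosen at desk scale: parameter
  recovery uses 50 replicate fields at 500–2,025 sites, cross-validation
  checks 50 fields at 100–400 sites, and the end-to-end pipeline smoke runs
  at 250–400 sites. These sizes give Monte-Carlo tolerances of ±15–20% on
  stochastic summaries.

## 8. Known limitations

* Kriging is ordinary (constant unknown mean) and planar: no external
  drift, co-kriging, Bayesian variogram inference, or spherical distances.
* The likelihood assumes Gaussianity of the (transformed) response; heavy
  residual tails bias the nugget upward.
* Variance partitioning fractions depend on the spatial-descriptor
  convention; with trend surfaces they absorb only broad-scale structure.
* The compact letter display is greedy; with many groups it may use more
  letters than the minimum, though never an inconsistent one.
* `best_subset_bic()` is exhaustive and intentionally refuses more than 20
  candidates.

## 9. A worked micro-example

```{r example}
cfg <- synthetic_config(n_sites = 400)
sim <- simulate_sites(cfg, seed = 1)
report <- run_pipeline(sim$sites, responses = "fb_ratio",
                       nu_candidates = 0.5, n_perm = 99, seed = 1)
report
```

The printed effective range, LOO summaries, and variance fractions are the
quantities discussed above, computed on a 400-site synthetic survey.
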