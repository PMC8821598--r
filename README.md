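# paleodiet

Quantifying how much of the variation in human paleodiet is driven by local
climate versus regional population size.

Bone-collagen stable isotopes are the standard individual-level record of
past diet: δ¹³C‰ tracks reliance on C3 versus C4 plants (and the foods of
animals eating them), while δ¹⁵N‰ tracks trophic level and marine input.
Archaeological compilations of such measurements — thousands of individuals
spread over millennia and strong elevation gradients — make it possible to
ask whether dietary change tracked changing local climates or changing
population pressure. `paleodiet` implements that comparison as a tested,
seeded, end-to-end pipeline for researchers in archaeometry, paleodemography
and human ecology.

## What the package computes

1. **Individual QC and zoning** — inclusion filters (weaning-age exclusion,
   collagen C:N acceptability with author overrides, pre-contact
   restriction) and classification into coastal (< 350 masl and < 15 km to
   coast), mid-elevation, and highland (> 3500 masl) zones.
2. **Radiocarbon calibration** — for a measurement `a ± e` against a curve
   (μ(t), σ(t)), the calendar-year mass is
   `p(t) ∝ N(a − ΔR; μ(t), √(e² + σ(t)² + σ_ΔR²))`, with marine reservoir
   offsets ΔR ± σ_ΔR, normalization, and support trimming.
3. **Dates-as-data demography** — per-zone composite kernel density
   ensembles: each of 1000 fits draws one calendar year per date from its
   calibrated density, weights dates by reciprocal site-bin size
   (hierarchical clustering, 200-yr cutoff), and smooths with a Gaussian
   kernel; optional taphonomic correction divides by the survival power law
   `n(t) = 5,726,442 (t + 2176.4)^(−1.3925309)`.
4. **Monte-Carlo exposure assignment** — each individual's date window is
   resampled 10,000 times (calibration-weighted when directly dated) and
   mapped onto gridded climate fields (mean temperature, temperature
   seasonality, precipitation, precipitation seasonality) and the KDE
   population proxy, yielding one covariate row per individual.
5. **Trend ensembles** — 10,000 penalized-spline (GAM, GCV-smoothed) fits
   per zone × isotope over resampled death years, aggregated to a central
   tendency with a 95 % band from within-fit and between-run variance.
6. **Driver models** — seeded random-forest regression of isotope values on
   the five covariates, tenfold cross-validation (RMSE, VEcv), collinearity
   screening, residual acf and Moran's I on inverse-distance weights.
7. **Effect decomposition** — centered partial dependence per covariate,
   Friedman's H interaction proportion
   `H = Σ(f − PD_j − PD_−j)² / Σ f²`, interaction-deducted explained sums of
   squares, per-mil effects `Effect(x_j) = √SS_deducted`, percent-of-total
   effects, and the cumulative climate vs demography comparison.
8. **Synthetic data** — a generator producing every input with known
   ground-truth covariate structure (effect shares, noise, a
   climate×climate interaction), so the whole pipeline is testable against
   a known answer.

## Worked example

```r
library(paleodiet)

bundle <- simulate_bundle(n_individuals = 600,
  dates_per_zone = c(coastal = 150, "mid-elevation" = 150, highland = 100),
  n_fits = 25, resolution = 5, seed = 42)

qc <- qc_filter(bundle$individuals)
exposures <- build_exposures(qc$individuals, bundle$climate,
                             bundle$ensembles, n_draws = 150, seed = 7)

keep <- !is.na(qc$individuals$d15N)
design <- exposures[keep, climate_vars()]
design$population <- exposures$kde_uncorrected[keep]
y <- qc$individuals$d15N[keep]

cv <- cross_validate(design, y, k = 10, num_trees = 200, seed = 1)
model <- fit_forest(design, y, num_trees = 200, seed = 1)
eff <- decompose_effects(model, cbind(design, zone = qc$individuals$zone[keep]),
                         n_iter = 25, m = 25, seed = 2, max_rows = 150)
cumulative_comparison(eff)
```

printed on this run:

```
VEcv = 46.5%, RMSE = 3.12 permil
<forest_model> n=549 trees=200 mtry=1 OOB R2=0.449
           zone climate_permil climate_percent demography_permil demography_percent ratio
1       coastal           13.1             122              4.64               35.7  2.82
2 mid-elevation           12.8             136              3.94               38.5  3.25
3      highland           11.6             134              4.47               45.7  2.60
```

Reading the output: the cross-validated forest explains 46 % of δ¹⁵N
variance at this small demonstration size (it rises toward the generator's
85 % signal share as sample size grows and date windows narrow); the
cumulative per-mil climate effect exceeds the demographic effect by a factor
of 2.6–3.3 in every elevation zone, recovering the climate-dominant
structure the generator was given (climate 0.75, population 0.10, noise
0.15 variance shares). Percentages are on the per-mil (square-root) scale
and deliberately do not sum to 100.

The staged pipeline form of the same analysis, with artifacts written per
stage, is

```r
run_pipeline(demo_config(seed = 1), "out/")
```

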