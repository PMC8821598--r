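---
title: "Climate and population as drivers of stable-isotope paleodiet: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Climate and population as drivers of stable-isotope paleodiet: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical machinery in `paleodiet`: the models
and their assumptions, the tunable parameters, what the synthetic-data
generator does and does not emulate, the numerical conventions, and the
design choices made where the method left room.

## The scientific question and the model

Individual diets, recorded as bone-collagen δ¹³C‰ and δ¹⁵N‰, are modeled as
a function of (a) the local climate an individual experienced during their
lifetime and (b) the relative size of the regional population at the time.
Because neither the death year nor the demographic history is observed
directly, both covariates carry structured uncertainty, which the pipeline
propagates by Monte Carlo:

* each individual's death year is known only to a date window (or, for
  directly radiocarbon-dated individuals, a calibrated calendar density);
* relative population is reconstructed from the temporal frequency of
  archaeological radiocarbon dates ("dates as data"), itself uncertain
  through calibration.

The driver model is a random-forest regression of the isotope value on five
covariate means (four climate variables and one population proxy). A forest
is used deliberately: responses may be non-linear and covariates interact,
and the attribution step must then separate each covariate's independent
effect from interaction-borne effect.

## Individual QC and elevation zones

Three filters are applied in a fixed, recorded order: known under-fives
(weaning trophic enrichment), collagen C:N failures, then Colonial-period
individuals. The order of the original filters is not recoverable from
published totals alone, so it is fixed here and reported in the QC report;
individuals of *unknown* age are retained, since exclusion requires positive
evidence of being under five. C:N acceptance is 2.9–3.6 outright, author
overrides admit roughly 2.6–3.6, and series-level validation admits samples
with no per-sample ratio.

Zoning uses strict thresholds: coastal below 350 masl *and* within 15 km of
the coast; highland above 3500 masl; otherwise mid-elevation, including the
exact boundary values. The three zones partition the (elevation, distance)
plane and approximate agro-marine, agrarian and agro-pastoral subsistence
regimes.

## Calibration conventions

Calibration evaluates, on a 1-yr calendar grid (configurable; the staged
pipeline uses coarser grids for speed), the Gaussian likelihood of the
measured age at the linearly interpolated curve mean, with measurement,
curve and reservoir variances added in quadrature. Marine dates have ΔR
subtracted from the measured age; non-marine dates ignore the ΔR fields
entirely. Mass below 1e−5 of the peak is trimmed and the density
renormalized — the common calibration-software convention, bounding support
size at negligible mass loss. One curve applies per date, chosen by the
marine flag; mixing hemispheric curves is out of scope. The density median
is defined as the smallest grid year reaching cumulative mass 0.5, matching
a resampling median as draws grow.

## Dates-as-data population proxies

Date QC removes duplicates by laboratory ID, ages over 15,000 ¹⁴C yr,
errors over 200 yr, and dates without coordinates (compilations known to be
exclusively coastal may be flagged exempt). Within each site, dates are
binned by complete-linkage hierarchical clustering on median calibrated
years, cut at 200 yr. Neither the binning metric nor the linkage is fixed by
prior practice; both are configurable and recorded in the ensemble
metadata. Bins weight dates by 1/bin-size at KDE time rather than sampling
one date per bin: this preserves within-bin chronological spread while
equalizing bin influence.

Each of the (default 1000) composite-KDE fits draws one calendar year per
date from its calibrated density and smooths with a Gaussian kernel. The
bandwidth is nowhere dictated by the method's sources; the default is 50 yr,
comparable to the 20-yr climate step, configurable and logged. Fits are
evaluated on a 0–7000 yBP grid at 20-yr steps (aligned with the climate
steps) and renormalized to integrate to one, so edge mass is folded back
proportionally. Taphonomic correction divides each fit by the relative
survival proportion `n(t)/n(t_ref)` with
`n(t) = 5,726,442 (t + 2176.4)^(−1.3925309)` and `t_ref` the youngest grid
year, then renormalizes; corrected and uncorrected proxies are both carried
through the rest of the analysis, as it is genuinely unclear which is more
accurate.

## Exposure assignment

Window draws use the calibrated density restricted to the window for dated
individuals and a uniform distribution over integer years otherwise (the
within-window death-date distribution is not otherwise identified). Sampled
years map to the nearest 20-yr step, ties toward the younger step, with no
temporal interpolation; coordinates map to the nearest climate-cell center,
mirroring extraction of a coarse raster at site coordinates. The analysis
span is clamped to 7000–140 yBP — the simulated climate ends at 140 yBP —
and windows reaching past it are truncated with a warning; this treatment
of terminal windows is a documented package choice.

One set of window draws per individual is shared across the four climate
variables and both KDE variants (population fit indices are drawn
independently); the joint sampling distribution is identical to independent
per-variable redraws at a fraction of the cost.

## Trend ensembles

Per zone × isotope, each of the (default 10,000) runs assigns every
individual one drawn death year and fits a cubic penalized spline
(basis dimension 10, configurable) with GCV-chosen smoothness. Runs are
aggregated pointwise into the mean prediction, mean standard error and
between-run standard deviation. The band is
`mean ± 1.96 √(mean_se² + mean_sd²)`, combining within-fit and between-run
variance; the exact band construction is an interpretation (the components
are therefore also emitted separately), and coverage on synthetic truth is
validated only loosely (≥ 85 %).

## Driver models and diagnostics

Forests use 500 trees, `floor(p/3)` candidate variables per split and
minimum node size 5 — the defaults of the underlying implementation — with a
fixed seed and one thread, so identical seeds give identical predictions.
Collinearity is screened at |r| ≥ 0.70 but flagged variables are retained;
the forest tolerates correlated predictors and the screen exists for
visibility. Model quality is reported as tenfold cross-validated RMSE and
VEcv (100 × (1 − SS_res/SS_tot) on out-of-fold predictions); out-of-bag R²
is also available on the model object since the two conventions are easy to
conflate. Temporal structure is summarized by the acf of residual means
binned to 20-yr steps of mean death year; spatial structure by Moran's I on
unstandardized inverse great-circle-distance weights with distances floored
at 1 km. The Moran statistic, its −1/(n−1) expectation, randomization
variance and two-sided normal p-value are computed in-package because the
usual library routine row-standardizes the weight matrix, which is a
different statistic from the unstandardized inverse-distance form used
here; the in-package form is cross-checked against that routine on
row-standardized weights, where the two coincide exactly.

## Effect decomposition

For covariate j, predictions `f_{i,k}` are formed over data rows i and a
grid of values v_k. The centered partial dependence `PD_j(v_k)` is the
row-mean centered across the grid; the complement `PD_−j(i)` is the
grid-mean centered across rows. Friedman's H,
`H = Σ(f − PD_j − PD_−j)² / Σ f²` on grand-mean-centered predictions,
is the proportion of j's effect carried by interactions: exactly 0 for
additive surfaces, approaching 1 for pure products. The verbal definitions
of the effect size and H (explained *sum of squares*; a *proportion*)
require squared forms, and the squared Friedman–Popescu statistics are what
is implemented; a configuration switch offers deduction by (1 − H²) instead
of (1 − H) since the wording of the deduction is ambiguous.

Per iteration (default 100), m = 100 values of x_j are resampled from the
zone's observed values, and the iteration records `SS_raw = Σ_k PD_j(v_k)²`,
H, `SS_deducted = SS_raw (1 − H)` and `SS_total = (1/n) Σ_{i,k} f_{i,k}²`.
Averaging over iterations, the per-mil effect is `√(mean SS_deducted)` and
the percent of total `100 √(mean SS_deducted) / √(mean SS_total)`. The
normalization — SS_raw summed over the m grid points, SS_total averaged over
rows and summed over grid replicates — reproduces per-mil effects of the
right order (units: ‰ of explained variation against totals of tens of ‰)
and is flagged as reverse-engineered; percentages are on the square-root
scale and do not sum to 100. An optional `max_rows` cap subsamples the rows
entering each iteration's partial-dependence averages, the usual cost
control for partial-dependence estimation.

A caveat this package makes explicit: training-data partial-dependence
effect sizes of a regression forest have a noise floor. A covariate with no
true effect and no correlation to any relevant covariate still shows a
nonzero per-mil effect — the forest memorizes residual noise along it, and
the square-root percent scale amplifies small sums of squares (a 1 % share
of variance reads as 10 %). In synthetic experiments at the package's
defaults this floor sits around 5–10 % on the percent scale for a pure-noise
covariate. Percent-of-total values in that band should therefore not be
over-interpreted as real influence; rank comparisons (cumulative climate vs
demography) are robust to the floor because it affects all covariates
similarly.

## The synthetic-data generator

The generator emulates the *structure* of the real inputs, not their
content: a 5-yr-step calibration curve whose mean is the identity plus a
smooth bounded sinusoidal wiggle (amplitude 30 ¹⁴C yr by default, bounded by
construction below 3 amplitudes); AR(1) climate series (coefficient 0.8)
around cell means with weak lat/lon gradients plus independent per-cell
intercepts — the intercepts keep cross-covariate correlations of the
resulting exposures below the 0.70 collinearity screen, as observed in the
real covariates; a two-bump relative population curve per zone; dates drawn
from it with Zipf-like site sizes (exercising binning) and a marine coastal
fraction with reservoir offsets baked in; and individuals whose isotope
values are an additive function of their true covariates plus one
temperature×precipitation interaction and Gaussian noise.

Effect shares are realized exactly: covariates are empirically standardized
within the generated sample and given coefficients `√(share) · scale`, so
each component's variance share is the intended one by construction. The
defaults place 0.75 of the response variance on climate (including the 0.05
interaction), 0.10 on population and 0.15 on noise — the climate-dominant
regime the pipeline is expected to detect. Default sample sizes mirror the
real compilations (1965 individuals; 1304/1843/810 dates per zone); about
9 % of individuals are directly dated; small fractions of under-fives,
out-of-range C:N and Colonial records exercise the filters.

What the generator does *not* emulate, and hence what passing tests cannot
show: real calibration-curve plateaus and reversals, real Andean
climatology or its spatial covariance, non-uniform within-window death-date
distributions, spatially biased sampling of sites, and isotope baselines or
diagenesis beyond the C:N rule. One visible consequence: the generator's
per-zone isotopic baselines (e.g. the coastal marine δ¹⁵N offset) are
intercepts the five covariates cannot fully absorb, so synthetic model
residuals show mild spatial autocorrelation by zone, unlike a well-specified
fit to real data.

## Numerical choices and problem sizes

Degenerate and edge cases are deliberate: zero-width windows are valid and
sample a single year; a single-run trend ensemble warns and reports zero
between-run spread; zero-variance cells yield zero z-scores with a warning;
an all-zero prediction surface yields H = 0 with a warning. Ties in
year-to-step mapping resolve toward the younger step. All randomness flows
from one master seed through named per-stage sub-seeds (kept within 32-bit
integer range), so every stage is independently reproducible and a pipeline
rerun is byte-identical.

The shipped defaults are the full study conditions (10,000 draws, 1000 KDE
fits, 10,000 trend runs, 100 × 100 effect iterations). The test-suite and
demo configurations scale these down — typically a few hundred individuals,
tens of KDE fits and trend runs, 25 × 25 effect iterations with a 150-row
partial-dependence subsample — sizes chosen so the full validation suite
runs comfortably on a laptop while every statistical property under test
remains detectable at its stated tolerance.
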