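---
title: "Estimating marsh aboveground biomass from annual maximum NDVI: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating marsh aboveground biomass from annual maximum NDVI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

marshAGB estimates the aboveground biomass (AGB) of herbaceous freshwater
marsh vegetation from a multi-year satellite NDVI record, and asks how its
year-to-year variation relates to monthly and annual climate. This vignette is
the package's own account of the science: the model, its assumptions, the
tunable parameters, what the synthetic scenes do and do not emulate, and the
numerical choices made where the design was genuinely open.

## The estimation model

The core biological assumption is that the annual maximum of a pixel's NDVI
trajectory, NDVI~max~, is a proxy for peak standing biomass: herbaceous marsh
vegetation in a cold temperate climate grows from essentially zero in spring
to a single mid-summer peak, and the dry mass standing at that peak is what a
July–September harvest measures. The calibration model is a power law

$$\mathrm{AGB} = a \cdot \mathrm{NDVI}_{max}^{\,b},$$

with AGB expressed as carbon density (g C/m²). Field observations enter as
sites of three replicated 1 m × 1 m quadrats; a site's value is the quadrat
mean, converted from dry mass to carbon with the fixed coefficient 0.45.

Four candidate forms (power, linear, exponential, logarithmic) are fitted and
the form with the largest coefficient of determination is selected. Two
details matter:

* **R² is computed on the original AGB scale** (`1 − SS_res/SS_tot`), for
  every form, so candidates are compared on the scale predictions are used.
* **The power and exponential fits are nonlinear least squares on the
  original scale**, initialised from the log-transformed ordinary
  least-squares fit. Fitting only on the log scale would estimate the
  *median* response under multiplicative noise and systematically bias the
  coefficient $a$ low on the data scale.

Validation reports the root mean squared error over the n samples and the
relative error, defined as the mean of the per-sample ratios
$100 \cdot |y_{obs} - y_{est}|/y_{obs}$. The alternative aggregate definition
(total absolute error over total observed) was considered and rejected: the
per-sample mean is what the validation formula expresses, and it weights
small and large sites equally. Samples with an observed value of exactly zero
are excluded from the relative error (their ratio is undefined) with a
warning.

## From rasters to regional carbon

* **Stable marsh mask.** Marsh extent maps from two epochs are intersected;
  only pixels mapped as marsh in both epochs enter the analysis, which
  removes areas converted by human activity between the epochs. A finer
  extent map (e.g. 30 m) is first brought to the analysis grid (e.g. 250 m)
  by majority rule — a target pixel is marsh when at least half of the
  non-missing fine pixels voting in it are marsh. Missing cells count as
  non-marsh in the intersection.
* **Maximum value compositing.** The within-year stack of 16-day NDVI
  composites is reduced to the per-pixel maximum. Missing composites are
  ignored; a pixel is missing only when every composite is missing. This is
  deliberately permissive: a single clear observation near the seasonal peak
  suffices, which is the rationale of maximum-value compositing in the first
  place.
* **Site–pixel pairing.** Each field site is paired with the NDVI~max~ of the
  pixel containing it, in the *sample's own year*. The alternative — pairing
  against a multi-year mean — would smooth over the very interannual signal
  the calibration is meant to capture. At pixel boundaries the
  nearest-pixel-centre rule applies, with ties resolved toward the smaller
  row then the smaller column index; pixels are half-open squares
  `[x, x+s) × (y−s, y]`, so every point belongs to exactly one pixel.
* **Regional aggregation.** The regional mean density is the mean over
  non-missing masked pixels; area is the masked pixel count times the pixel
  area; the total carbon stock is mean density × area, reported in Tg C
  (10¹² g). The identity `total = mean × area` holds to machine precision by
  construction.

Predictions clip NDVI to [0, 1] before exponentiation: composite noise can
push observed NDVI marginally above 1, and a power of a negative base is
undefined.

## Trends and climate correlations

Per-pixel trends use the least-squares slope of the annual series
($\theta_{slope}$, units per year) computed from the closed-form normal
equations. Significance is the classical two-sided t test of the slope on
n − 2 degrees of freedom; a series with zero residual variance gets p = 0 by
convention. The same t reference is used for correlation significance. The
method's authors marked p < 0.05 / p < 0.01 without naming a test; the t test
is the conventional default for both statistics, and a simulation check in
the test suite confirms its type-I error is nominal (rejection rate within
[0.03, 0.07] at α = 0.05 for white-noise series of length 21).

Station climate is interpolated to the analysis grid by **ordinary kriging**
with a spherical semivariogram fitted to the 12-bin empirical semivariogram
by pair-count-weighted least squares (nugget allowed; empirical cutoff at
half the maximum pairwise distance). The kriging system uses semivariances
with zero on the diagonal, which keeps the predictor exact at station
locations even with a non-zero nugget. Stations are aggregated to the period
first (annual precipitation = sum of months, annual temperature = mean of
months), then interpolated; the alternative order (interpolate monthly, then
aggregate surfaces) is equivalent for these linear aggregations up to
variogram-fit differences, and aggregating first costs 12× less computation.
Degenerate inputs are handled conservatively: fewer than three stations falls
back to inverse-distance weighting with a warning, and a singular kriging
system is retried once with metre-scale coordinate jitter before falling
back.

The correlation table (Annual + 12 months × precipitation, T~mean~, T~max~,
T~min~) correlates *regional mean series*: the AGB series averaged over the
mask against each climate variable's kriged surface averaged over the mask.
The alternative — averaging the per-pixel correlation maps — yields a
quantity that is not a correlation coefficient and has no significance test;
single coefficients per cell alongside separate pixel-wise maps imply the
regional-series reading. No multiple-testing correction is applied across
the 13 × 4 cells or across pixels; this mirrors the method as published and
is a known caveat — at α = 0.05 roughly 2–3 of 52 independent null cells
would be starred by chance.

The south/north split recomputes the table for masked pixels at or below
versus above a threshold latitude (default 47° N), using each sub-region's
own regional series.

## The synthetic scenes

Real marsh-extent maps, MODIS NDVI and station records are not bundled;
instead `generate_scene()` builds complete scenes with known ground truth:

* **Masks**: two epochs thresholded from one smooth random suitability field,
  so their intersection is spatially coherent rather than salt-and-pepper.
* **NDVI**: a clipped sinusoidal seasonal curve (`sin⁴` shape over the year,
  winter floor 0.05) peaking mid-summer, so the annual maximum is
  well-defined and attained at a composite date; additive Gaussian
  observation noise (default sd 0.02, a typical post-compositing residual
  noise level for 16-day products), clipped to the valid NDVI range.
* **Latent AGB**: a smooth baseline field mapped through the true power law
  (defaults a = 643.57, b = 4.2474), plus a per-pixel linear trend (default
  uniform 2.47 g C/m²/a) centred on the middle year, plus a regional July
  temperature sensitivity (default 15 g C/m² per °C — about a 5% response of
  a typical 300 g C/m² marsh to a 1 °C summer anomaly). The July anomaly
  series is residualised against the year index, so the configured trend is
  *exactly* the generating trend of latent AGB and `truth_expected_trend()`
  is exact for any coupling.
* **Quadrats**: latent AGB / 0.45 perturbed by multiplicative lognormal noise
  with median 1 (default coefficient of variation 0.15). Median-preserving
  noise keeps the power law exact in the median; biomass stays positive and
  heteroscedastic, as field replicates are. The within-site replicate
  variance of real quadrats is not published, so the default is a simulation
  knob chosen to be field-plausible, not an estimate.
* **Stations**: 21 locations sampling smooth climate fields (linear gradient
  + one Gaussian bump per variable) with a monsoon-season precipitation
  cycle, a strongly continental temperature cycle (annual mean ≈ 3.2 °C),
  linear trends, and spatially uniform interannual anomalies — uniform so
  that each (variable, period, year) field stays smooth and station values
  equal the truth exactly, which is what the kriging exactness contract
  needs. T~min~/T~max~ are deterministic seasonal offsets from T~mean~, so
  the ordering invariant holds by construction.

What the scenes deliberately do **not** emulate: cloud/aerosol contamination
flags, view-angle effects, mixed pixels at marsh edges, station relocation
or missingness, and spatially structured interannual climate anomalies.
Passing tests therefore demonstrate that the *pipeline machinery* is correct
and well-calibrated under clean-but-noisy conditions, not that the power-law
model is right for any particular real marsh.

## Problem sizes and numerical choices

The default scene is a 100 × 100 grid of 250 m pixels straddling 47° N, 21
years × 23 composites, 21 stations and 16 sites sampled in 2013–2017 — the
shape of the study the package re-implements. The test suite mostly uses
24 × 24 scenes, which exercise every code path at a few percent of the cost;
the full-scene checks run once in the acceptance tests.

Two noise regimes appear in the checks, and the distinction is deliberate.
Parameter recovery of the calibration is quantified at the realistic
field-noise level (cv = 0.15, 16 sites: median absolute relative error of
both parameters is under 10%, and exact recovery at cv = 0). The end-to-end
trend-map check instead uses a low-noise scene (cv = 0.05, NDVI sd = 0.01):
with only 16 calibration sites, the sampling error of the fitted curve — and
occasionally the selection of a neighbouring functional form with nearly
equal R² but different curvature — propagates a common multiplicative error
of order ±10% into every pixel's trend, which is a property of the 16-site
study design, not of the trend estimator. The low-noise scene isolates what
the check is about: that maximum-value compositing, prediction and the
per-pixel slope machinery recover an injected signal.

Other numerical details: the variogram fit runs L-BFGS-B with non-negativity
bounds and a range bounded into (1% , 4×) of the empirical cutoff;
`fit_candidates()` flags a failed or non-finite fit per form instead of
raising, and selection errors only if every form failed; ties in model
selection break toward fewer parameters, then the fixed form order power <
linear < exponential < logarithmic; pixels need all years present to enter
trend or correlation maps (no imputation). Scene generation, the pipeline
and the simulators draw from a single seeded stream and restore the caller's
RNG state, so identical configurations give bit-identical scenes and
byte-identical summary JSON.

## Known limitations

* The calibration extrapolates below the sites' NDVI range for sparse marsh
  pixels; non-power forms can then predict negative biomass. Predictions are
  reported as fitted, without clamping — regional means at realistic
  parameters are unaffected, but per-pixel values below the calibration
  domain should not be over-interpreted.
* Kriging assumes second-order stationarity with an isotropic spherical
  variogram; no elevation co-kriging or external drift, although real
  terrain would warrant it.
* No uncertainty propagation from calibration error into the regional carbon
  totals; the correlation table inherits the usual caveats of short (21-year)
  series and multiple comparisons.
* The package performs no reprojection: all rasters are assumed
  co-registered on one grid, and lon/lat conversion exists only for the
  built-in local equirectangular labelling used by the synthetic scenes.
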