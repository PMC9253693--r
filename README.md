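# marshAGB

Estimation of marsh aboveground biomass (AGB) carbon from satellite NDVI time
series, with trend and climate attribution — built for wetland carbon
analysts who have a multi-year NDVI record, marsh extent maps from two
epochs, a handful of destructively-sampled field sites, and monthly station
climate, and who want regional carbon stocks, per-pixel trends and
monthly/annual climate correlations out the other end.

## The model

Herbaceous marsh vegetation in cold temperate climates grows to a single
mid-summer biomass peak, and the annual maximum NDVI of a pixel
(NDVI<sub>max</sub>, obtained by maximum value compositing of 16-day
composites) tracks that peak. The calibration at the package's core is the
power law

> AGB = a · NDVI<sub>max</sub><sup>b</sup>  (g C/m²)

fitted by nonlinear least squares to field sites (three 1 m × 1 m quadrats
per site, averaged, dry mass × 0.45 → carbon) paired with their pixel's
NDVI<sub>max</sub> in the sample's own year. Power, linear, exponential and
logarithmic candidates are compared by R² on the original AGB scale and the
best is applied over the *stable marsh mask* — the intersection of the two
epoch extent maps. Downstream, per-pixel least-squares trends
(θ<sub>slope</sub>, g C/m²/a, with t-based significance) and Pearson
correlations against ordinary-kriged station climate (Annual + each month ×
precipitation, T<sub>mean</sub>, T<sub>max</sub>, T<sub>min</sub>) quantify
change and its climate drivers, including a south/north split at a latitude
threshold.

Because real MODIS/station/extent data are not redistributable, the package
ships a first-class synthetic-scene generator (`generate_scene()`) with a
known power law, seasonal NDVI dynamics, smooth climate fields and
configurable observation noise, so every stage is testable against ground
truth.

## Worked example

```r
library(marshAGB)

scene <- generate_scene(scene_config(nrows = 40, ncols = 40, seed = 1))
mask  <- stable_marsh_mask(scene$mask_epoch1, scene$mask_epoch2)
ndvi  <- scene_ndvi_max_stack(scene)            # annual NDVI_max, 2000-2020
sites <- pair_sites_ndvi(add_carbon_density(scene$sites), ndvi)

model <- select_best(fit_candidates(sites))
model
#> agb_model (power): a = 449.3777, b = 3.4334, R2 = 0.7817, RMSE = 12.99, rel.err = 8.70% (n = 16)

agb <- predict_agb_stack(model, ndvi, mask)
agb_mean <- marsh_raster(scene$grid, apply(agb$values, c(1, 2), mean))
str(regional_summary(agb_mean, mask))
#> List of 4
#>  $ mean_density: num 111
#>  $ area_m2     : num 70375000
#>  $ total_TgC   : num 0.00784
#>  $ n_pixels    : int 1126

pixelwise_map(agb, mask = mask, kind = "trend")
#> stat_map (trend, AGB): median 2.077, 1126 pixels, 95.7% with p < 0.05

clim <- regional_climate_series(scene$stations, scene$grid, mask,
                                scene$config$years,
                                periods = c("Annual", "January", "July"))
correlation_table(regional_series(agb, mask), clim)
#>   period precip   tmean    tmax    tmin
#>   Annual  0.189   0.405   0.405   0.405
#>  January -0.274  0.524*  0.524*  0.524*
#>     July  0.160 0.837** 0.837** 0.837**
```

Reading the output: the 16 noisy sites calibrate a power model (here with
parameters pulled toward the generating a = 643.57, b = 4.2474 within the
sampling error of 16 sites); the 1126 stable-marsh pixels of this small scene
hold ~0.008 Tg C at a mean density of 111 g C/m²; the trend map recovers the
injected upward trend (2.47 g C/m²/a generated, 2.08 estimated at this noise
level), significant in 96% of pixels; and the correlation table recovers the
injected July-temperature dependence as the strongest, double-starred cells.
`*` and `**` mark p < 0.05 and p < 0.01.

The same analysis runs end-to-end from a config file, writing ASCII-grid
rasters, CSV tables and a JSON summary:

```sh
Rscript scripts/run_pipeline.R --config run.yml --seed 1
```

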