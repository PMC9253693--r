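## Synthetic scenes with known ground truth: marsh masks, seasonal NDVI stacks,
## station climate and quadrat AGB samples, generated so that every downstream
## stage (masking, compositing, calibration, trends, kriging, correlation) has
## a closed-form expected answer.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Configuration of a synthetic marsh scene
#'
#' Defines the study conditions a scene emulates: a 250 m analysis grid
#' straddling 47 deg N, a 21-year (2000-2020) NDVI series at 16-day cadence
#' (23 composites per year), 21 climate stations, and 16 field sites sampled
#' in 2013-2017 with three 1 m x 1 m quadrats each. The generating biomass
#' model is the power law `AGB = true_a * NDVI_max^true_b` in g C/m2.
#'
#' @param nrows,ncols grid dimensions (>= 2 each)
#' @param pixel_size pixel size in metres
#' @param years calendar years of the NDVI series
#' @param composites_per_year within-year NDVI composites (23 for 16-day cadence)
#' @param n_stations number of meteorological stations
#' @param n_sites number of field AGB sites
#' @param site_years years in which field sites are sampled
#' @param true_a power-law coefficient (g C/m2), > 0
#' @param true_b power-law exponent (dimensionless), > 0
#' @param ndvi_noise_sd additive observation noise on each NDVI composite
#' @param agb_noise_cv coefficient of variation of the multiplicative lognormal
#'   quadrat noise (median-preserving, so the power law is exact in the median)
#' @param agb_trend per-pixel linear trend of latent AGB in g C/m2 per year;
#'   a scalar (uniform field) or an `nrows x ncols` matrix
#' @param july_tmean_effect sensitivity of latent AGB to the regional July
#'   mean-temperature anomaly, g C/m2 per deg C
#' @param july_effect_north_multiplier multiplies `july_tmean_effect` for
#'   pixels north of `lat_split` (used to inject a regional contrast)
#' @param lat_split latitude (deg N) separating the southern/northern regions
#' @param july_anom_sd standard deviation (deg C) of the interannual July
#'   temperature anomaly driving AGB
#' @param temp_anom_sd interannual anomaly sd (deg C) for other month/variable
#'   combinations
#' @param precip_anom_sdlog lognormal sdlog of interannual precipitation
#'   multipliers
#' @param temp_trend linear trend of monthly temperatures, deg C per year
#' @param precip_trend linear trend of annual precipitation, mm per year
#'   (distributed over months in proportion to the monthly normals)
#' @param ndvi_base_range range of the smooth baseline peak-NDVI field
#' @param seed integer seed; identical configurations give identical scenes
#' @return an object of class `scene_config`
#' @export
scene_config <- function(nrows = 100, ncols = 100, pixel_size = 250,
                         years = 2000:2020, composites_per_year = 23,
                         n_stations = 21, n_sites = 16,
                         site_years = 2013:2017,
                         true_a = 643.57, true_b = 4.2474,
                         ndvi_noise_sd = 0.02, agb_noise_cv = 0.15,
                         agb_trend = 2.47,
                         july_tmean_effect = 15,
                         july_effect_north_multiplier = 1,
                         lat_split = 47,
                         july_anom_sd = 1.0, temp_anom_sd = 1.2,
                         precip_anom_sdlog = 0.25,
                         temp_trend = 0.04, precip_trend = 1.0,
                         ndvi_base_range = c(0.55, 0.9),
                         seed = 42) {
  cfg <- list(nrows = as.integer(nrows), ncols = as.integer(ncols),
              pixel_size = pixel_size, years = as.integer(years),
              composites_per_year = as.integer(composites_per_year),
              n_stations = as.integer(n_stations),
              n_sites = as.integer(n_sites),
              site_years = as.integer(site_years),
              true_a = true_a, true_b = true_b,
              ndvi_noise_sd = ndvi_noise_sd, agb_noise_cv = agb_noise_cv,
              agb_trend = agb_trend,
              july_tmean_effect = july_tmean_effect,
              july_effect_north_multiplier = july_effect_north_multiplier,
              lat_split = lat_split,
              july_anom_sd = july_anom_sd, temp_anom_sd = temp_anom_sd,
              precip_anom_sdlog = precip_anom_sdlog,
              temp_trend = temp_trend, precip_trend = precip_trend,
              ndvi_base_range = ndvi_base_range,
              seed = as.integer(seed))
  class(cfg) <- "scene_config"
  validate_scene_config(cfg)
  cfg
}

validate_scene_config <- function(cfg) {
  bad <- function(field, why)
    stop(sprintf("invalid SceneConfig: field '%s' %s", field, why),
         call. = FALSE)
  if (cfg$nrows < 2) bad("nrows", "must be >= 2")
  if (cfg$ncols < 2) bad("ncols", "must be >= 2")
  if (cfg$pixel_size <= 0) bad("pixel_size", "must be > 0")
  if (cfg$composites_per_year < 1) bad("composites_per_year", "must be >= 1")
  if (length(cfg$years) < 1) bad("years", "must be non-empty")
  if (cfg$true_a <= 0) bad("true_a", "must be > 0")
  if (cfg$true_b <= 0) bad("true_b", "must be > 0")
  if (cfg$ndvi_noise_sd < 0) bad("ndvi_noise_sd", "must be >= 0")
  if (cfg$agb_noise_cv < 0) bad("agb_noise_cv", "must be >= 0")
  if (cfg$n_stations < 1) bad("n_stations", "must be >= 1")
  if (cfg$n_sites < 1) bad("n_sites", "must be >= 1")
  if (!length(intersect(cfg$site_years, cfg$years)))
    bad("site_years", "must overlap years")
  if (!is.matrix(cfg$agb_trend) && length(cfg$agb_trend) != 1)
    bad("agb_trend", "must be a scalar or an nrows x ncols matrix")
  if (is.matrix(cfg$agb_trend) &&
      !all(dim(cfg$agb_trend) == c(cfg$nrows, cfg$ncols)))
    bad("agb_trend", "matrix dimensions must match the grid")
  invisible(cfg)
}

scene_grid <- function(cfg) {
  # grid centred on the reference point so rows straddle lat_split
  half_x <- cfg$ncols * cfg$pixel_size / 2
  half_y <- cfg$nrows * cfg$pixel_size / 2
  raster_grid(cfg$nrows, cfg$ncols, origin_x = -half_x, origin_y = half_y,
              pixel_size = cfg$pixel_size,
              crs_id = sprintf("local:lon0=133,lat0=%g", cfg$lat_split))
}

## smooth random field in [0, 1]: sum of Gaussian bumps, min-max scaled
smooth_field01 <- function(nrows, ncols, n_bumps = 6) {
  r <- matrix(rep(seq_len(nrows), ncols), nrows, ncols) / nrows
  c <- matrix(rep(seq_len(ncols), each = nrows), nrows, ncols) / ncols
  f <- matrix(0, nrows, ncols)
  cr <- runif(n_bumps); cc <- runif(n_bumps)
  amp <- runif(n_bumps, -1, 1); wid <- runif(n_bumps, 0.15, 0.45)
  for (k in seq_len(n_bumps))
    f <- f + amp[k] * exp(-((r - cr[k])^2 + (c - cc[k])^2) / (2 * wid[k]^2))
  rng <- range(f)
  if (diff(rng) < .Machine$double.eps) return(matrix(0.5, nrows, ncols))
  (f - rng[1]) / diff(rng)
}

## monthly climate normals for a cold temperate monsoon plain
climate_normals <- function() {
  m <- 1:12
  tmean <- 3.2 - 21 * cos(2 * pi * (m - 1) / 12)        # Jan ~ -17.8, Jul ~ 24.2
  w <- exp(-((m - 7.2) / 1.8)^2)
  precip <- 550 * w / sum(w)                            # ~550 mm/yr, monsoon peak
  dmin <- 5 + 2 * cos(2 * pi * (m - 1) / 12)            # tmean - tmin offset
  dmax <- 5.5 + 1.5 * cos(2 * pi * (m - 1) / 12)        # tmax - tmean offset
  list(tmean = tmean, precip = precip, dmin = dmin, dmax = dmax)
}

#' Generate a complete synthetic scene
#'
#' Produces two epoch marsh masks, a (year, composite) NDVI stack, station
#' climate records and field quadrat samples, together with a `truth` record
#' holding the generating parameters and latent fields. NDVI follows a clipped
#' sinusoidal seasonal curve peaking mid-summer, so the annual maximum is
#' well-defined; latent AGB at the seasonal peak follows the configured power
#' law plus a per-pixel linear trend and a detrended regional July-temperature
#' anomaly (detrending keeps the configured trend exactly the generating
#' trend). Quadrat biomasses are latent AGB / 0.45 perturbed by
#' median-preserving multiplicative lognormal noise.
#'
#' @param cfg a [scene_config()]
#' @return an object of class `marsh_scene`: list with `config`, `grid`,
#'   `mask_epoch1`, `mask_epoch2`, `ndvi_series` (4-D array
#'   nrows x ncols x composites x years), `stations` and `sites` data frames,
#'   and `truth`
#' @export
generate_scene <- function(cfg) {
  validate_scene_config(cfg)
  grid <- scene_grid(cfg)
  ny <- length(cfg$years)
  nr <- cfg$nrows; nc <- cfg$ncols; ncomp <- cfg$composites_per_year
  with_seed(cfg$seed, {
    ## --- marsh masks: two epochs derived from one smooth suitability field
    suit <- smooth_field01(nr, nc, n_bumps = 8)
    pert <- smooth_field01(nr, nc, n_bumps = 8)
    m1 <- (suit > stats::quantile(suit, 0.25)) * 1
    m2 <- ((suit + 0.15 * (pert - 0.5)) > stats::quantile(suit, 0.30)) * 1
    mask1 <- marsh_raster(grid, m1)
    mask2 <- marsh_raster(grid, m2)
    stable <- (m1 > 0.5) & (m2 > 0.5)

    ## --- latent AGB and peak NDVI
    base01 <- smooth_field01(nr, nc, n_bumps = 6)
    ndvi_base <- cfg$ndvi_base_range[1] + diff(cfg$ndvi_base_range) * base01
    agb_base <- cfg$true_a * ndvi_base^cfg$true_b
    trend_field <- if (is.matrix(cfg$agb_trend)) cfg$agb_trend
                   else matrix(cfg$agb_trend, nr, nc)
    lat_row <- pixel_latitudes(grid)
    north <- matrix(lat_row > cfg$lat_split, nr, nc)
    beta_field <- cfg$july_tmean_effect *
      ifelse(north, cfg$july_effect_north_multiplier, 1)

    i_cent <- seq_len(ny) - (ny + 1) / 2
    raw_anom <- stats::rnorm(ny, 0, cfg$july_anom_sd)
    ## residualise against the year index: the anomaly adds no trend of its own
    july_anom <- if (ny >= 3)
      stats::residuals(stats::lm(raw_anom ~ seq_len(ny))) else raw_anom * 0
    july_anom <- as.numeric(july_anom)

    ndvi_peak <- array(0, c(nr, nc, ny))
    latent_agb <- array(0, c(nr, nc, ny))
    for (i in seq_len(ny)) {
      agb <- agb_base + trend_field * i_cent[i] + beta_field * july_anom[i]
      agb <- pmax(agb, 1)
      peak <- pmin(pmax((agb / cfg$true_a)^(1 / cfg$true_b), 0.05), 0.98)
      ndvi_peak[, , i] <- peak
      latent_agb[, , i] <- cfg$true_a * peak^cfg$true_b
    }

    ## --- seasonal composites with observation noise
    f <- (seq_len(ncomp) - 0.5) / ncomp
    shape <- sin(pi * f)^4              # peak mid-year; equals 1 when a
    shape_max <- max(shape)             # composite falls exactly at mid-season
    ndvi_winter <- 0.05
    ndvi_series <- array(0, c(nr, nc, ncomp, ny))
    for (i in seq_len(ny)) {
      peak <- ndvi_peak[, , i]
      for (j in seq_len(ncomp)) {
        v <- ndvi_winter + (peak - ndvi_winter) * shape[j]
        if (cfg$ndvi_noise_sd > 0)
          v <- v + stats::rnorm(nr * nc, 0, cfg$ndvi_noise_sd)
        ndvi_series[, , j, i] <- pmin(pmax(v, -0.2), 1.0)
      }
    }
    true_ndvi_max <- ndvi_winter + (ndvi_peak - ndvi_winter) * shape_max

    ## --- field sites inside the stable mask
    stable_idx <- which(stable)
    if (length(stable_idx) < cfg$n_sites)
      stop("stable mask too small to place sites", call. = FALSE)
    site_cells <- sample(stable_idx, cfg$n_sites)
    site_row <- ((site_cells - 1) %% nr) + 1
    site_col <- ((site_cells - 1) %/% nr) + 1
    yrs_avail <- intersect(cfg$site_years, cfg$years)
    site_year <- yrs_avail[((seq_len(cfg$n_sites) - 1) %% length(yrs_avail)) + 1]
    xy <- rowcol_to_xy(grid, site_row, site_col)
    ll <- xy_to_lonlat(grid, xy$x, xy$y)
    sdlog <- sqrt(log(1 + cfg$agb_noise_cv^2))
    q <- matrix(0, cfg$n_sites, 3)
    for (s in seq_len(cfg$n_sites)) {
      iy <- match(site_year[s], cfg$years)
      dry <- latent_agb[site_row[s], site_col[s], iy] / 0.45
      mult <- if (sdlog > 0) stats::rlnorm(3, 0, sdlog) else rep(1, 3)
      q[s, ] <- dry * mult
    }
    sites <- data.frame(site_id = sprintf("S%02d", seq_len(cfg$n_sites)),
                        lon = ll$lon, lat = ll$lat, year = site_year,
                        quadrat1_g = q[, 1], quadrat2_g = q[, 2],
                        quadrat3_g = q[, 3])

    ## --- stations sampling smooth climate fields
    ext_x <- c(grid$origin_x, grid$origin_x + nc * grid$pixel_size)
    ext_y <- c(grid$origin_y - nr * grid$pixel_size, grid$origin_y)
    st_x <- runif(cfg$n_stations, ext_x[1] + 0.02 * diff(ext_x),
                  ext_x[2] - 0.02 * diff(ext_x))
    st_y <- runif(cfg$n_stations, ext_y[1] + 0.02 * diff(ext_y),
                  ext_y[2] - 0.02 * diff(ext_y))
    nrm <- climate_normals()
    ## spatial structure: linear gradient + one Gaussian bump per variable
    bump <- function(x, y, cx, cy, w) exp(-((x - cx)^2 + (y - cy)^2) / (2 * w^2))
    tb <- list(cx = runif(1, ext_x[1], ext_x[2]),
               cy = runif(1, ext_y[1], ext_y[2]),
               w = 0.4 * diff(ext_x))
    pb <- list(cx = runif(1, ext_x[1], ext_x[2]),
               cy = runif(1, ext_y[1], ext_y[2]),
               w = 0.4 * diff(ext_x))
    tmean_sp <- function(x, y) -6e-5 * y + 1.0 * bump(x, y, tb$cx, tb$cy, tb$w)
    precip_sp <- function(x, y) 0.3 * (2 * bump(x, y, pb$cx, pb$cy, pb$w) - 1) +
      2e-6 * x
    ## interannual regional anomalies (spatially uniform, so per-period fields
    ## stay smooth); July tmean carries the AGB-coupled anomaly
    t_anom <- matrix(stats::rnorm(ny * 12, 0, cfg$temp_anom_sd), ny, 12)
    t_anom[, 7] <- july_anom
    p_mult <- matrix(stats::rlnorm(ny * 12, 0, cfg$precip_anom_sdlog), ny, 12)
    st_id <- rep(sprintf("M%02d", seq_len(cfg$n_stations)), each = ny * 12)
    st_xr <- rep(st_x, each = ny * 12); st_yr <- rep(st_y, each = ny * 12)
    yr <- rep(rep(cfg$years, each = 12), cfg$n_stations)
    mo <- rep(rep(1:12, ny), cfg$n_stations)
    iy <- match(yr, cfg$years)
    tmean <- nrm$tmean[mo] + tmean_sp(st_xr, st_yr) +
      cfg$temp_trend * (iy - 1) + t_anom[cbind(iy, mo)]
    precip <- pmax(0, (nrm$precip[mo] + cfg$precip_trend * (iy - 1) *
                         nrm$precip[mo] / sum(nrm$precip)) *
                     (1 + precip_sp(st_xr, st_yr)) * p_mult[cbind(iy, mo)])
    stll <- xy_to_lonlat(grid, st_xr, st_yr)
    stations <- data.frame(station_id = st_id, lon = stll$lon, lat = stll$lat,
                           year = yr, month = mo,
                           precip_mm = precip,
                           tmin_c = tmean - nrm$dmin[mo],
                           tmax_c = tmean + nrm$dmax[mo],
                           tmean_c = tmean)

    truth <- list(true_a = cfg$true_a, true_b = cfg$true_b,
                  trend_field = trend_field, beta_field = beta_field,
                  july_anom = july_anom,
                  ndvi_max = true_ndvi_max, latent_agb = latent_agb,
                  stable_mask = stable * 1,
                  climate = list(normals = nrm, temp_trend = cfg$temp_trend,
                                 precip_trend = cfg$precip_trend,
                                 tmean_bump = tb, precip_bump = pb))

    structure(list(config = cfg, grid = grid,
                   mask_epoch1 = mask1, mask_epoch2 = mask2,
                   ndvi_series = ndvi_series,
                   stations = stations, sites = sites, truth = truth),
              class = "marsh_scene")
  })
}

#' @export
print.marsh_scene <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(paste0("marsh_scene: %d x %d grid, %d years x %d composites, ",
                     "%d stations, %d sites (seed %d)\n"),
              cfg$nrows, cfg$ncols, length(cfg$years), cfg$composites_per_year,
              cfg$n_stations, cfg$n_sites, cfg$seed))
  invisible(x)
}

#' Generating AGB trend at a pixel
#'
#' Oracle accessor: returns the linear trend (g C/m2 per year) with which the
#' latent AGB series at a pixel was generated. Errors for pixels outside the
#' stable marsh mask, where no AGB series is defined.
#'
#' @param scene a [generate_scene()] result
#' @param row,col 1-based pixel indices
#' @return slope in g C/m2 per year
#' @export
truth_expected_trend <- function(scene, row, col) {
  stopifnot(inherits(scene, "marsh_scene"))
  if (row < 1 || row > scene$grid$nrows || col < 1 || col > scene$grid$ncols)
    stop("pixel outside grid", call. = FALSE)
  if (!isTRUE(scene$truth$stable_mask[row, col] > 0.5))
    stop("pixel outside the stable marsh mask", call. = FALSE)
  scene$truth$trend_field[row, col]
}

#' Simulate a stand-alone calibration set
#'
#' Draws `n` (NDVI_max, AGB carbon density) pairs from the power law
#' `AGB = true_a * NDVI_max^true_b`, with three quadrat dry-biomass values per
#' site perturbed by median-preserving multiplicative lognormal noise of the
#' given coefficient of variation. Used to study parameter recovery of the
#' calibration stage in isolation.
#'
#' @param n number of sites
#' @param true_a,true_b generating power-law parameters
#' @param agb_noise_cv quadrat noise coefficient of variation
#' @param ndvi_range range from which site NDVI_max values are drawn uniformly
#' @param seed integer seed
#' @return data frame with columns `site_id`, `ndvi_max`, `quadrat1_g`,
#'   `quadrat2_g`, `quadrat3_g`, `agb_density` (0.45 x mean of quadrats)
#' @export
simulate_calibration_pairs <- function(n = 16, true_a = 643.57,
                                       true_b = 4.2474, agb_noise_cv = 0.15,
                                       ndvi_range = c(0.45, 0.9), seed = 1) {
  with_seed(seed, {
    x <- runif(n, ndvi_range[1], ndvi_range[2])
    dry <- true_a * x^true_b / 0.45
    sdlog <- sqrt(log(1 + agb_noise_cv^2))
    q <- matrix(if (sdlog > 0) stats::rlnorm(3 * n, 0, sdlog) else 1, n, 3) * dry
    data.frame(site_id = sprintf("S%02d", seq_len(n)), ndvi_max = x,
               quadrat1_g = q[, 1], quadrat2_g = q[, 2], quadrat3_g = q[, 3],
               agb_density = 0.45 * rowMeans(q))
  })
}

#' Write a scene's inputs to disk as plain-text files
#'
#' Masks and NDVI composites go to ESRI ASCII grids, stations and sites to
#' CSV, and the scalar truth parameters to JSON (`truth.json`, with the grid
#' geometry needed to re-read the rasters).
#'
#' @param scene a [generate_scene()] result
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_scene <- function(scene, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "ndvi"), showWarnings = FALSE)
  write_asc(scene$mask_epoch1, file.path(dir, "mask_epoch1.asc"))
  write_asc(scene$mask_epoch2, file.path(dir, "mask_epoch2.asc"))
  cfg <- scene$config
  for (i in seq_along(cfg$years))
    for (j in seq_len(cfg$composites_per_year))
      write_asc(marsh_raster(scene$grid, scene$ndvi_series[, , j, i]),
                file.path(dir, "ndvi",
                          sprintf("ndvi_%d_%02d.asc", cfg$years[i], j)))
  utils::write.csv(scene$stations, file.path(dir, "stations.csv"),
                   row.names = FALSE)
  utils::write.csv(scene$sites, file.path(dir, "sites.csv"), row.names = FALSE)
  tr <- scene$truth
  jsonlite::write_json(
    list(true_a = tr$true_a, true_b = tr$true_b,
         mean_trend = mean(tr$trend_field), crs_id = scene$grid$crs_id,
         years = cfg$years, composites_per_year = cfg$composites_per_year),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
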