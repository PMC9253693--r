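test_that("scene generation is deterministic given the seed", {
  cfg <- scene_config(nrows = 12, ncols = 12, years = 2000:2005,
                      site_years = 2002:2004, n_stations = 5, n_sites = 6,
                      seed = 4)
  s1 <- generate_scene(cfg)
  s2 <- generate_scene(cfg)
  expect_identical(s1$ndvi_series, s2$ndvi_series)
  expect_identical(s1$stations, s2$stations)
  expect_identical(s1$sites, s2$sites)
  expect_identical(s1$truth$trend_field, s2$truth$trend_field)
})

test_that("invalid configurations are rejected naming the offending field", {
  expect_error(scene_config(true_a = -1), "true_a")
  expect_error(scene_config(composites_per_year = 0), "composites_per_year")
  expect_error(scene_config(ndvi_noise_sd = -0.1), "ndvi_noise_sd")
  expect_error(scene_config(nrows = 1), "nrows")
  expect_error(scene_config(agb_trend = matrix(0, 3, 3)), "agb_trend")
})

test_that("a paper-shaped configuration yields the expected scene dimensions", {
  sc <- small_scene()
  expect_equal(nrow(sc$sites), 16)
  expect_equal(length(unique(sc$stations$station_id)), 21)
  expect_equal(dim(sc$ndvi_series), c(24, 24, 23, 21))
  expect_true(all(sc$sites$year %in% 2013:2017))
  expect_true(all(sc$ndvi_series >= -0.2 & sc$ndvi_series <= 1.0))
  # station records respect tmin <= tmean <= tmax and non-negative precip
  expect_true(all(sc$stations$tmin_c <= sc$stations$tmean_c))
  expect_true(all(sc$stations$tmean_c <= sc$stations$tmax_c))
  expect_true(all(sc$stations$precip_mm >= 0))
})

test_that("all generated sites fall inside the stable marsh mask", {
  sc <- small_scene()
  stable <- stable_marsh_mask(sc$mask_epoch1, sc$mask_epoch2)
  xy <- lonlat_to_xy(sc$grid, sc$sites$lon, sc$sites$lat)
  rc <- xy_nearest_pixel(sc$grid, xy$x, xy$y)
  expect_true(all(stable$values[cbind(rc$row, rc$col)] == 1))
})

test_that("noise-free sites satisfy the generating power law exactly", {
  sc <- noise_free_scene()
  stk <- scene_ndvi_max_stack(sc)
  sites <- pair_sites_ndvi(add_carbon_density(sc$sites), stk)
  expect_equal(sites$agb_density,
               sc$config$true_a * sites$ndvi_max^sc$config$true_b,
               tolerance = 1e-10)
})

test_that("truth_expected_trend returns the generating trend field", {
  cfg0 <- small_cfg(agb_trend = 0, july_tmean_effect = 0)
  sc0 <- generate_scene(cfg0)
  in_mask <- which(sc0$truth$stable_mask > 0.5, arr.ind = TRUE)
  k <- in_mask[1, ]
  expect_equal(truth_expected_trend(sc0, k[1], k[2]), 0)

  cfg2 <- small_cfg(agb_trend = 2.0, july_tmean_effect = 0)
  sc2 <- generate_scene(cfg2)
  in2 <- which(sc2$truth$stable_mask > 0.5, arr.ind = TRUE)
  expect_true(all(apply(in2[1:10, ], 1, function(rc)
    truth_expected_trend(sc2, rc[1], rc[2])) == 2.0))

  out <- which(sc2$truth$stable_mask < 0.5, arr.ind = TRUE)[1, ]
  expect_error(truth_expected_trend(sc2, out[1], out[2]), "mask")
})

test_that("stored trend truth matches a per-pixel least-squares refit of latent AGB", {
  set.seed(5)
  trend <- matrix(runif(24 * 24, -3, 3), 24, 24)
  sc <- generate_scene(small_cfg(agb_trend = trend, july_tmean_effect = 0,
                                 ndvi_noise_sd = 0, agb_noise_cv = 0))
  idx <- which(sc$truth$stable_mask > 0.5, arr.ind = TRUE)
  idx <- idx[seq(1, nrow(idx), length.out = 40), , drop = FALSE]
  n <- length(sc$config$years)
  for (k in seq_len(nrow(idx))) {
    y <- sc$truth$latent_agb[idx[k, 1], idx[k, 2], ]
    refit <- unname(coef(lm(y ~ seq_len(n)))[2])   # brute-force OLS oracle
    expect_equal(truth_expected_trend(sc, idx[k, 1], idx[k, 2]), refit,
                 tolerance = 1e-8)
  }
})

test_that("calibration-set simulator honours the noise-free limit and cv", {
  p0 <- simulate_calibration_pairs(n = 20, agb_noise_cv = 0, seed = 2)
  expect_equal(p0$agb_density, 643.57 * p0$ndvi_max^4.2474, tolerance = 1e-12)
  p <- simulate_calibration_pairs(n = 2000, agb_noise_cv = 0.3, seed = 2)
  mult <- p$quadrat1_g / (643.57 * p$ndvi_max^4.2474 / 0.45)
  expect_equal(sd(mult) / mean(mult), 0.3, tolerance = 0.05)
  expect_equal(median(mult), 1, tolerance = 0.03)  # median-preserving noise
})

test_that("scene inputs round-trip through the plain-text writers", {
  cfg <- scene_config(nrows = 8, ncols = 8, years = 2001:2003,
                      composites_per_year = 3, n_stations = 4, n_sites = 3,
                      site_years = 2001:2003, seed = 6)
  sc <- generate_scene(cfg)
  dir <- withr::local_tempdir()
  write_scene(sc, dir)
  back <- read_scene_inputs(dir)
  expect_equal(back$mask_epoch1$values, sc$mask_epoch1$values)
  expect_equal(back$ndvi_series, sc$ndvi_series, tolerance = 1e-8)
  expect_equal(back$sites$quadrat2_g, sc$sites$quadrat2_g, tolerance = 1e-6)
  expect_equal(back$config$years, 2001:2003)
})
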