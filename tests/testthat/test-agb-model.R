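test_that("site carbon density is 0.45 times the quadrat mean", {
  expect_equal(site_carbon_density(c(100, 100, 100)), 45.0)
  expect_equal(site_carbon_density(c(0, 0, 0)), 0.0)
  expect_equal(site_carbon_density(c(80, 100, 120)), 45.0)
  expect_error(site_carbon_density(c(100, 100)), "three quadrats")
  expect_error(site_carbon_density(c(100, -1, 100)), "non-negative")
})

test_that("noise-free power-law pairs recover the generating parameters", {
  x <- seq(0.3, 0.9, length.out = 16)
  pairs <- data.frame(ndvi_max = x, agb_density = 643.57 * x^4.2474)
  models <- fit_candidates(pairs)
  expect_equal(models$power$a, 643.57, tolerance = 1e-7)
  expect_equal(models$power$b, 4.2474, tolerance = 1e-7)
  expect_equal(models$power$r_squared, 1, tolerance = 1e-10)
  best <- select_best(models)
  expect_equal(best$form, "power")
})

test_that("exact linear data give the linear form R^2 = 1", {
  x <- seq(0.2, 0.9, length.out = 10)
  models <- fit_candidates(data.frame(ndvi_max = x, agb_density = 2 * x))
  expect_equal(models$linear$r_squared, 1, tolerance = 1e-10)
  expect_equal(models$linear$b, 2, tolerance = 1e-8)
})

test_that("noisy power fit agrees with a dense grid-search RSS minimiser", {
  pairs <- add_carbon_density(simulate_calibration_pairs(n = 16,
                                                         agb_noise_cv = 0.15,
                                                         seed = 17))
  m <- fit_candidates(pairs)$power
  # independent oracle: residual sum of squares over an (a, b) grid
  rss <- function(a, b) sum((pairs$agb_density - a * pairs$ndvi_max^b)^2)
  agrid <- seq(m$a * 0.7, m$a * 1.3, length.out = 121)
  bgrid <- seq(m$b * 0.7, m$b * 1.3, length.out = 121)
  vals <- outer(agrid, bgrid, Vectorize(rss))
  k <- which(vals == min(vals), arr.ind = TRUE)[1, ]
  # the NLS solution must beat or match the best grid point
  expect_lte(rss(m$a, m$b), vals[k[1], k[2]] * (1 + 1e-8))
  # and sit within one grid step of the grid optimum
  expect_lt(abs(agrid[k[1]] - m$a), diff(agrid[1:2]) * 1.5)
  expect_lt(abs(bgrid[k[2]] - m$b), diff(bgrid[1:2]) * 1.5)
})

test_that("degenerate calibration input flags fits instead of raising", {
  pairs <- data.frame(ndvi_max = rep(0.5, 5), agb_density = c(1, 2, 3, 4, 5))
  models <- fit_candidates(pairs)
  expect_true(all(!vapply(models, function(m) isTRUE(m$ok), logical(1))))
  expect_error(select_best(models), "selection failed")
})

test_that("model selection prefers the highest R^2 with the stated tie order", {
  mk <- function(form, r2) {
    m <- fit_candidates(data.frame(ndvi_max = c(0.2, 0.5, 0.8),
                                   agb_density = c(10, 60, 300)))[[form]]
    m$r_squared <- r2
    m
  }
  expect_equal(select_best(list(mk("power", 0.86), mk("linear", 0.60)))$form,
               "power")
  expect_equal(select_best(list(mk("linear", 0.9)))$form, "linear")
  # equal R^2, equal parameter count: earlier form in the canonical order wins
  expect_equal(select_best(list(mk("logarithmic", 0.8),
                                mk("exponential", 0.8)))$form, "exponential")
  expect_equal(select_best(list(mk("linear", 0.8), mk("power", 0.8)))$form,
               "power")
})

test_that("validation metrics follow their per-sample definitions", {
  m <- structure(list(form = "linear", a = 0, b = 1, ok = TRUE),
                 class = "agb_model")
  # perfect predictions
  v <- validate_model(m, data.frame(ndvi_max = c(1, 2), agb_density = c(1, 2)))
  expect_equal(v$rmse, 0)
  expect_equal(v$relative_error_pct, 0)
  # obs (100, 200) vs est (110, 180): RMSE = sqrt((100+400)/2), rel err = 10%
  v <- validate_model(m, data.frame(ndvi_max = c(110, 180),
                                    agb_density = c(100, 200)))
  expect_equal(v$rmse, sqrt(250), tolerance = 1e-12)
  expect_equal(v$relative_error_pct, 10.0, tolerance = 1e-12)
  # zero observations are excluded from relative error with a warning
  expect_warning(
    v <- validate_model(m, data.frame(ndvi_max = c(0, 110),
                                      agb_density = c(0, 100))),
    "excluded")
  expect_equal(v$relative_error_pct, 10.0)
})

test_that("raster prediction applies the power law inside the mask only", {
  g <- unit_grid(4)
  paper_model <- structure(list(form = "power", a = 643.57, b = 4.2474,
                                ok = TRUE), class = "agb_model")
  ndvi <- marsh_raster(g, matrix(runif(16, 0.1, 1.2), 4, 4))
  ndvi$values[1, 1] <- 1.0
  ndvi$values[2, 1] <- 0
  ndvi$values[3, 1] <- NA
  mask <- marsh_raster(g, matrix(1, 4, 4)); mask$values[4, 4] <- 0
  out <- predict_raster(paper_model, ndvi, mask)
  expect_equal(out$values[1, 1], 643.57)
  expect_equal(out$values[2, 1], 0)
  expect_true(is.na(out$values[3, 1]))
  expect_true(is.na(out$values[4, 4]))
  # pixelwise loop oracle, with NDVI clipped to [0, 1]
  for (r in 1:4) for (c in 1:4) {
    if ((r == 4 && c == 4) || is.na(ndvi$values[r, c])) next
    x <- min(max(ndvi$values[r, c], 0), 1)
    expect_equal(out$values[r, c], 643.57 * x^4.2474)
  }
  # monotone in NDVI for the power form
  expect_true(all(diff(predict(paper_model, seq(0, 1, 0.01))) >= 0))
  bad <- structure(list(form = "power", a = NA, b = NA, ok = FALSE),
                   class = "agb_model")
  expect_error(predict_raster(bad, ndvi, mask), "not .* fitted")
})

test_that("regional summary reproduces the area-times-density arithmetic", {
  # uniform density over a region the size of the study's marsh area
  n <- 40
  px <- sqrt(6.0e8 / n^2)            # mask area exactly 6.0e8 m2
  g <- raster_grid(n, n, 0, n * px, px)
  agb <- marsh_raster(g, 282.05)
  mask <- marsh_raster(g, 1)
  s <- regional_summary(agb, mask)
  expect_equal(s$area_m2, 6.0e8)
  expect_equal(s$mean_density, 282.05)
  expect_equal(s$total_TgC, 282.05 * 6.0e8 * 1e-12, tolerance = 1e-12)
  expect_equal(round(s$total_TgC, 2), 0.17)
  # single 250 m pixel of density 1: 62500 g = 6.25e-8 Tg
  g1 <- raster_grid(1, 1, 0, 250, 250)
  s1 <- regional_summary(marsh_raster(g1, 1), marsh_raster(g1, 1))
  expect_equal(s1$total_TgC, 6.25e-8)
  # random masked raster vs explicit sum/count loop
  set.seed(41)
  g2 <- unit_grid(12)
  vals <- matrix(runif(144, 0, 500), 12, 12); vals[2, 5] <- NA
  msk <- random_mask(g2)
  s2 <- regional_summary(marsh_raster(g2, vals), msk)
  acc <- c(); npx <- 0
  for (r in 1:12) for (c in 1:12) if (msk$values[r, c] == 1) {
    npx <- npx + 1
    if (!is.na(vals[r, c])) acc <- c(acc, vals[r, c])
  }
  expect_equal(s2$mean_density, mean(acc))
  expect_equal(s2$area_m2, npx * 1)
  expect_equal(s2$total_TgC, mean(acc) * npx * 1e-12)
  expect_error(regional_summary(marsh_raster(g2, vals),
                                marsh_raster(g2, 0)), "empty region")
})
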