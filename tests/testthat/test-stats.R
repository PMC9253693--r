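test_that("theta_slope matches the closed-form OLS slope", {
  expect_equal(theta_slope(rep(5, 21)), 0)
  expect_equal(theta_slope(2 * (1:21) + 7), 2)                 # exact line
  expect_true(is.na(theta_slope(c(1, 2))))                     # n < 3
  expect_true(is.na(theta_slope(c(1, NA, 3, 4))))
  # independent normal-equations oracle on random series
  set.seed(61)
  for (k in 1:300) {
    n <- sample(3:30, 1)
    y <- rnorm(n)
    i <- seq_len(n)
    X <- cbind(1, i)
    beta <- solve(t(X) %*% X, t(X) %*% y)                      # normal equations
    expect_lt(abs(theta_slope(y) - beta[2]), 1e-10)
  }
})

test_that("trend significance behaves like the classical t test", {
  # strong exact trend with tiny noise is overwhelmingly significant
  set.seed(62)
  y <- 5 * (1:21) + rnorm(21, 0, 0.01)
  expect_lt(slope_significance(y), 1e-6)
  # agreement with lm's summary on random series
  for (k in 1:50) {
    y <- rnorm(21)
    p_lm <- summary(lm(y ~ i, data = data.frame(i = 1:21)))$coefficients[2, 4]
    expect_equal(slope_significance(y), p_lm, tolerance = 1e-10)
  }
  # an exact line has zero residual variance: p = 0 by convention
  expect_equal(slope_significance(3 * (1:10) + 1), 0)
})

test_that("null trend series are rejected at close to the nominal rate", {
  set.seed(63)
  p <- replicate(400, slope_significance(rnorm(21)))
  rate <- mean(p < 0.05)
  expect_gte(rate, 0.02)
  expect_lte(rate, 0.09)
  # p-values under the null are close to uniform
  expect_gt(suppressWarnings(ks.test(p, "punif")$p.value), 0.01)
})

test_that("pearson_r reproduces the product-moment formula and its symmetries", {
  x <- rnorm(21)
  expect_equal(pearson_r(x, x), 1.0)
  expect_equal(pearson_r(x, -3 * x + 5), -1.0)
  expect_true(is.na(pearson_r(x, rep(2, 21))))                 # zero variance
  expect_error(pearson_r(x, rnorm(5)), "lengths differ")
  set.seed(64)
  for (k in 1:100) {
    a <- rnorm(21); b <- rnorm(21)
    direct <- sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
    expect_lt(abs(pearson_r(a, b) - direct), 1e-12)
    # affine invariance (positive scale) and antisymmetry under negation
    expect_equal(pearson_r(2.5 * a + 1, b), pearson_r(a, b), tolerance = 1e-12)
    expect_equal(pearson_r(a, -b), -pearson_r(a, b), tolerance = 1e-12)
  }
})

test_that("pixel-wise maps equal scalar calls in a double loop", {
  set.seed(65)
  g <- unit_grid(20)
  yrs <- 2000:2014
  A <- array(rnorm(20 * 20 * 15), c(20, 20, 15))
  B <- array(rnorm(20 * 20 * 15), c(20, 20, 15))
  A[3, 3, 5] <- NA                      # incomplete series is skipped
  mask <- random_mask(g, 0.7)
  sa <- annual_stack(g, yrs, A)
  sb <- annual_stack(g, yrs, B)
  tmap <- pixelwise_map(sa, mask = mask, kind = "trend")
  cmap <- pixelwise_map(sa, sb, mask, kind = "correlation")
  for (r in 1:20) for (c in 1:20) {
    if (mask$values[r, c] == 0) {
      expect_true(is.na(tmap$values$values[r, c]))
      expect_true(is.na(cmap$values$values[r, c]))
    } else if (anyNA(A[r, c, ])) {
      expect_true(is.na(tmap$values$values[r, c]))
    } else {
      expect_equal(tmap$values$values[r, c], theta_slope(A[r, c, ]),
                   tolerance = 1e-12)
      expect_equal(tmap$p_values$values[r, c], slope_significance(A[r, c, ]),
                   tolerance = 1e-12)
      expect_equal(cmap$values$values[r, c], pearson_r(A[r, c, ], B[r, c, ]),
                   tolerance = 1e-12)
    }
  }
  # identical stacks correlate perfectly everywhere
  self <- pixelwise_map(sa, sa, mask, kind = "correlation")
  inside <- mask$values == 1 & apply(!is.na(A), c(1, 2), all)
  expect_true(all(abs(self$values$values[inside] - 1) < 1e-12))
  # correlation values stay in [-1, 1], p-values in [0, 1]
  expect_true(all(abs(cmap$values$values) <= 1, na.rm = TRUE))
  expect_true(all(cmap$p_values$values >= 0 & cmap$p_values$values <= 1,
                  na.rm = TRUE))
  # year misalignment raises an error naming the offending years
  sb2 <- annual_stack(g, 2001:2015, B)
  expect_error(pixelwise_map(sa, sb2, mask, kind = "correlation"), "2015")
})

test_that("regional series averages masked pixels per year", {
  g <- unit_grid(8)
  yrs <- 2001:2005
  arr <- array(rnorm(8 * 8 * 5), c(8, 8, 5))
  stk <- annual_stack(g, yrs, arr)
  # uniform stack
  u <- annual_stack(g, yrs, array(7, c(8, 8, 5)))
  expect_equal(unname(regional_series(u, marsh_raster(g, 1))), rep(7, 5))
  # a single masked pixel returns that pixel's series
  m1 <- marsh_raster(g, 0); m1$values[4, 6] <- 1
  expect_equal(unname(regional_series(stk, m1)), arr[4, 6, ])
  # random stack vs loop mean
  set.seed(66)
  msk <- random_mask(g)
  rs <- regional_series(stk, msk)
  for (i in 1:5) {
    acc <- c()
    for (r in 1:8) for (c in 1:8)
      if (msk$values[r, c] == 1) acc <- c(acc, arr[r, c, i])
    expect_equal(unname(rs[i]), mean(acc))
  }
})

test_that("the correlation table flags significance and detects identity", {
  set.seed(67)
  yrs <- 2000:2020
  agb <- rnorm(21, 100, 10)
  clim <- lapply(c(precip = 1, tmean = 2, tmax = 3, tmin = 4), function(k) {
    m <- matrix(rnorm(13 * 21), 13, 21,
                dimnames = list(c("Annual", month.name), yrs))
    m
  })
  clim$tmean["July", ] <- agb                     # identical series
  tab <- correlation_table(agb, clim)
  expect_equal(nrow(tab), 13)
  expect_equal(tab$r_tmean[tab$period == "July"], 1.0)
  expect_equal(tab$sig_tmean[tab$period == "July"], "**")
  expect_true(all(abs(tab$r_precip) <= 1))
  expect_error(correlation_table(agb[1:20], clim), "alignment")
})

test_that("white-noise climate series are rarely flagged", {
  set.seed(68)
  flagged <- replicate(60, {
    agb <- rnorm(21)
    clim <- list(precip = matrix(rnorm(13 * 21), 13, 21,
                                 dimnames = list(c("Annual", month.name), NULL)))
    tab <- correlation_table(agb, clim)
    mean(tab$sig_precip != "")
  })
  expect_lt(mean(flagged), 0.10)   # ~5% nominal rate per cell
})

test_that("latitude split separates regions and preserves homogeneous structure", {
  sc <- cached_scene("split", small_cfg(july_effect_north_multiplier = 3,
                                        seed = 12))
  mask <- stable_marsh_mask(sc$mask_epoch1, sc$mask_epoch2)
  stk <- scene_ndvi_max_stack(sc)
  model <- select_best(fit_candidates(pair_sites_ndvi(add_carbon_density(sc$sites),
                                                      stk)))
  agb <- predict_agb_stack(model, stk, mask)
  sp <- latitude_split(agb, sc$stations, mask, threshold_deg = 47,
                       periods = c("Annual", "July"))
  r_n <- sp$north$r_tmean[sp$north$period == "July"]
  r_s <- sp$south$r_tmean[sp$south$period == "July"]
  # the injected effect is three times stronger north of the threshold
  expect_gt(r_n, r_s)
  expect_gt(r_n, 0.5)
  # submasks partition the stable mask
  expect_equal(sp$south_mask$values + sp$north_mask$values, mask$values)
  # an all-north threshold empties the southern region
  expect_error(latitude_split(agb, sc$stations, mask, threshold_deg = 40,
                              periods = "July"), "south")
})
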