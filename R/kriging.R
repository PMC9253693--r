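## Station aggregation and ordinary kriging of monthly/annual climate onto the
## analysis grid. Variogram: spherical model fitted to a 12-bin empirical
## semivariogram by pair-count-weighted least squares.

CLIMATE_VARS <- c("precip", "tmean", "tmax", "tmin")
PERIODS <- c("Annual", month.name)

climate_column <- function(variable) {
  switch(variable, precip = "precip_mm", tmean = "tmean_c",
         tmax = "tmax_c", tmin = "tmin_c",
         stop(sprintf("unknown climate variable '%s'", variable), call. = FALSE))
}

#' Aggregate one station's record to a period value
#'
#' Monthly periods return the stored value. Annual precipitation is the sum of
#' the 12 monthly values; annual temperature is their mean. A missing month in
#' an annual request yields `NA` (missing-value signal).
#'
#' @param stations long-format station table (`station_id`, `year`, `month`,
#'   `precip_mm`, `tmin_c`, `tmax_c`, `tmean_c`)
#' @param station_id station identifier
#' @param year calendar year
#' @param period `"Annual"`, a month number 1-12, or a month name
#' @param variable one of `"precip"`, `"tmean"`, `"tmax"`, `"tmin"`
#' @return the aggregated value, or `NA` if any required month is missing
#' @export
station_period_value <- function(stations, station_id, year, period, variable) {
  col <- climate_column(variable)
  rec <- stations[stations$station_id == station_id & stations$year == year, ]
  if (identical(period, "Annual") || identical(period, "annual")) {
    v <- rec[[col]][match(1:12, rec$month)]
    if (any(is.na(v))) return(NA_real_)
    if (variable == "precip") sum(v) else mean(v)
  } else {
    m <- if (is.character(period)) match(period, month.name) else as.integer(period)
    if (is.na(m) || m < 1 || m > 12)
      stop(sprintf("unknown period '%s'", period), call. = FALSE)
    v <- rec[[col]][match(m, rec$month)]
    if (length(v) == 0) NA_real_ else v
  }
}

#' Station values for one (variable, year, period)
#' @inheritParams station_period_value
#' @param grid a [raster_grid()] used to project station lon/lat
#' @return data frame `station_id`, `x`, `y`, `value` (missing values dropped)
#' @export
station_period_table <- function(stations, grid, year, period, variable) {
  ids <- unique(stations$station_id)
  pos <- stations[match(ids, stations$station_id), c("lon", "lat")]
  xy <- lonlat_to_xy(grid, pos$lon, pos$lat)
  val <- vapply(ids, function(id)
    station_period_value(stations, id, year, period, variable), numeric(1))
  out <- data.frame(station_id = ids, x = xy$x, y = xy$y, value = val)
  out[!is.na(out$value), , drop = FALSE]
}

## ---- variogram -------------------------------------------------------------

#' Empirical semivariogram
#'
#' Bins the squared half-differences of all station pairs by separation
#' distance, up to a cutoff (default: half the maximum pairwise distance).
#'
#' @param x,y station coordinates (projected metres)
#' @param values station values
#' @param n_bins number of distance bins
#' @param cutoff maximum lag distance considered
#' @return data frame `dist` (mean pair distance per bin), `gamma`, `npairs`
#' @export
empirical_variogram <- function(x, y, values, n_bins = 12, cutoff = NULL) {
  d <- as.vector(stats::dist(cbind(x, y)))
  g <- as.vector(stats::dist(values))^2 / 2
  if (is.null(cutoff)) cutoff <- max(d) / 2
  keep <- d <= cutoff & d > 0
  d <- d[keep]; g <- g[keep]
  bins <- cut(d, breaks = seq(0, cutoff, length.out = n_bins + 1),
              include.lowest = TRUE)
  out <- data.frame(dist = tapply(d, bins, mean),
                    gamma = tapply(g, bins, mean),
                    npairs = as.integer(table(bins)))
  out[!is.na(out$gamma), , drop = FALSE]
}

spherical_gamma <- function(h, nugget, psill, range_) {
  g <- ifelse(h >= range_, nugget + psill,
              nugget + psill * (1.5 * h / range_ - 0.5 * (h / range_)^3))
  g[h <= 0] <- 0
  g
}

#' Fit a spherical variogram model by weighted least squares
#'
#' Minimises the pair-count-weighted squared deviation between the empirical
#' semivariogram and the spherical model (nugget, partial sill, range), with
#' all parameters constrained non-negative.
#'
#' @param emp empirical variogram from [empirical_variogram()]
#' @param max_dist distance scale used to bound/initialise the range
#' @return list `nugget`, `psill`, `range`
#' @export
fit_spherical_variogram <- function(emp, max_dist = max(emp$dist)) {
  sill0 <- max(mean(emp$gamma), .Machine$double.eps)
  obj <- function(p) {
    g <- spherical_gamma(emp$dist, p[1], p[2], p[3])
    sum(emp$npairs * (emp$gamma - g)^2)
  }
  fit <- stats::optim(c(0, sill0, max_dist * 0.7), obj, method = "L-BFGS-B",
                      lower = c(0, 1e-12 * sill0, max_dist * 0.01),
                      upper = c(sill0 * 2, sill0 * 4, max_dist * 4))
  list(nugget = fit$par[1], psill = fit$par[2], range = fit$par[3])
}

cdist <- function(x1, y1, x2, y2) {
  sqrt(outer(x1, x2, "-")^2 + outer(y1, y2, "-")^2)
}

grid_centres <- function(grid) {
  rowcol_to_xy(grid,
               rep(seq_len(grid$nrows), grid$ncols),
               rep(seq_len(grid$ncols), each = grid$nrows))
}

idw_points <- function(st, px, py, power = 2) {
  d <- cdist(px, py, st$x, st$y)
  w <- 1 / pmax(d, 1e-9)^power
  pred <- as.vector((w %*% st$value) / rowSums(w))
  exact <- apply(d, 1, which.min)
  hit <- d[cbind(seq_along(exact), exact)] < 1e-9
  pred[hit] <- st$value[exact[hit]]
  pred
}

krige_solve <- function(st, px, py) {
  m <- nrow(st)
  emp <- empirical_variogram(st$x, st$y, st$value)
  vg <- fit_spherical_variogram(emp)
  D <- cdist(st$x, st$y, st$x, st$y)
  A <- rbind(cbind(spherical_gamma(D, vg$nugget, vg$psill, vg$range), 1),
             c(rep(1, m), 0))
  D0 <- cdist(st$x, st$y, px, py)
  B <- rbind(spherical_gamma(D0, vg$nugget, vg$psill, vg$range),
             rep(1, length(px)))
  ## prediction points coinciding with a station: gamma = 0 there, which
  ## makes ordinary kriging exact at the data points even with a nugget
  B[seq_len(m), ][D0 < 1e-9] <- 0
  W <- solve(A, B)
  as.vector(crossprod(W[seq_len(m), , drop = FALSE], st$value))
}

#' Interpolate station values to the grid by ordinary kriging
#'
#' Ordinary kriging with a spherical semivariogram fitted to the 12-bin
#' empirical variogram by weighted least squares. The predictor is exact at
#' station locations. With fewer than 3 stations the function falls back to
#' inverse-distance weighting (with a warning); a singular kriging system is
#' retried once with jittered coordinates, then also falls back.
#'
#' @param st data frame with `x`, `y`, `value` (projected metres); e.g. from
#'   [station_period_table()]
#' @param grid target [raster_grid()]
#' @return `krige_field`: a [marsh_raster()] covering every grid pixel
#' @export
krige_field <- function(st, grid) {
  ctr <- grid_centres(grid)
  pred <- krige_points(st, ctr$x, ctr$y, jitter_scale = grid$pixel_size)
  marsh_raster(grid, matrix(pred, grid$nrows, grid$ncols))
}

#' @rdname krige_field
#' @param px,py prediction coordinates (projected metres)
#' @param jitter_scale length scale of the coordinate jitter used when
#'   retrying a singular system
#' @return `krige_points`: numeric vector of predictions at (`px`, `py`)
#' @export
krige_points <- function(st, px, py, jitter_scale = 1) {
  st <- st[is.finite(st$value), , drop = FALSE]
  ## collapse duplicated locations to their mean
  key <- paste(signif(st$x, 12), signif(st$y, 12))
  if (anyDuplicated(key)) {
    st <- do.call(rbind, lapply(split(st, key), function(d)
      data.frame(x = d$x[1], y = d$y[1], value = mean(d$value))))
  }
  m <- nrow(st)
  if (m < 3) {
    warning("fewer than 3 stations: falling back to inverse-distance weighting")
    return(idw_points(st, px, py))
  }
  if (stats::sd(st$value) == 0)
    return(rep(st$value[1], length(px)))
  res <- try(krige_solve(st, px, py), silent = TRUE)
  if (inherits(res, "try-error")) {
    jit <- st
    eps <- 1e-6 * max(jitter_scale, 1)
    jit$x <- jit$x + stats::runif(m, -eps, eps)
    jit$y <- jit$y + stats::runif(m, -eps, eps)
    res <- try(krige_solve(jit, px, py), silent = TRUE)
    if (inherits(res, "try-error")) {
      warning("singular kriging system: falling back to inverse-distance weighting")
      res <- idw_points(st, px, py)
    }
  }
  res
}

#' Kriged climate surface for one variable and period
#'
#' Aggregates stations to the requested (year, period) first, then
#' interpolates the aggregated values (aggregate-then-interpolate).
#'
#' @inheritParams station_period_table
#' @return list with `variable`, `year`, `period`, `surface` (a
#'   [marsh_raster()])
#' @export
krige_climate <- function(stations, grid, year, period, variable) {
  st <- station_period_table(stations, grid, year, period, variable)
  list(variable = variable, year = year, period = period,
       surface = krige_field(st, grid))
}

#' Regional climate series from kriged surfaces
#'
#' For every period (Annual + 12 months) and variable, kriges the station
#' aggregate to the grid for each year and averages the surface over the
#' masked pixels, yielding the regional series used by the correlation table.
#'
#' @param stations long-format station table
#' @param grid analysis [raster_grid()]
#' @param mask boolean [marsh_raster()]
#' @param years years to cover
#' @param variables climate variables to include
#' @param periods periods to include (default Annual + all months)
#' @return named list (by variable) of matrices `length(periods) x
#'   length(years)` with rownames `periods`
#' @export
regional_climate_series <- function(stations, grid, mask, years,
                                    variables = CLIMATE_VARS,
                                    periods = PERIODS) {
  inside <- !is.na(mask$values) & mask$values > 0.5
  ctr <- grid_centres(grid)
  px <- ctr$x[as.vector(inside)]
  py <- ctr$y[as.vector(inside)]
  out <- lapply(variables, function(v) {
    m <- matrix(NA_real_, length(periods), length(years),
                dimnames = list(periods, years))
    for (p in seq_along(periods))
      for (i in seq_along(years)) {
        st <- station_period_table(stations, grid, years[i], periods[p], v)
        ## the regional mean needs the surface at masked pixels only
        m[p, i] <- mean(krige_points(st, px, py,
                                     jitter_scale = grid$pixel_size),
                        na.rm = TRUE)
      }
    m
  })
  names(out) <- variables
  out
}
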