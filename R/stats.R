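## Per-pixel and regional trend and correlation analysis: least-squares slope
## of annual series, t-based significance, Pearson correlation, pixel-wise
## maps, the Annual+12-month correlation table and the latitude split.

#' Least-squares slope of an ordered annual series
#'
#' The per-pixel trend statistic: with year index i = 1..n,
#' `(n * sum(i * y_i) - sum(i) * sum(y_i)) / (n * sum(i^2) - (sum(i))^2)`,
#' i.e. the ordinary least-squares slope in units per year.
#'
#' @param y numeric series in year order (no missing values; n >= 3)
#' @return slope in units per year; `NA` when `n < 3` or any value is missing
#' @export
theta_slope <- function(y) {
  n <- length(y)
  if (n < 3 || anyNA(y)) return(NA_real_)
  i <- seq_len(n)
  (n * sum(i * y) - sum(i) * sum(y)) / (n * sum(i^2) - sum(i)^2)
}

## vectorised over rows of Y (pixels x years); returns slope and p-value
slope_stats_matrix <- function(Y) {
  n <- ncol(Y)
  i <- seq_len(n)
  Si <- sum(i); Sii <- sum(i^2)
  denom <- n * Sii - Si^2
  Sy <- rowSums(Y)
  Siy <- as.vector(Y %*% i)
  slope <- (n * Siy - Si * Sy) / denom
  intercept <- Sy / n - slope * Si / n
  res <- Y - outer(slope, i) - intercept
  rss <- rowSums(res^2)
  sxx <- Sii - Si^2 / n
  se <- sqrt(rss / (n - 2) / sxx)
  tstat <- ifelse(se > 0, slope / se, Inf)
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[se == 0] <- 0
  list(slope = slope, p = p)
}

#' Two-sided p-value of a series' linear trend
#'
#' Classical t test of the least-squares slope: `t = slope / SE(slope)` on
#' `n - 2` degrees of freedom. A series with zero residual variance (an exact
#' line) returns p = 0 by convention.
#'
#' @param y numeric series in year order (n >= 3, no missing values)
#' @return two-sided p-value
#' @export
slope_significance <- function(y) {
  n <- length(y)
  if (n < 3 || anyNA(y)) return(NA_real_)
  slope_stats_matrix(matrix(y, 1))$p
}

#' Pearson correlation coefficient
#'
#' Direct product-moment formula
#' `sum((x - xbar)(y - ybar)) / sqrt(sum((x - xbar)^2) * sum((y - ybar)^2))`.
#' Zero variance in either argument yields `NA` (missing-value signal).
#'
#' @param x,y numeric series of equal length (n >= 3)
#' @return correlation in [-1, 1], or `NA`
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y))
    stop("series lengths differ", call. = FALSE)
  if (length(x) < 3 || anyNA(x) || anyNA(y)) return(NA_real_)
  dx <- x - mean(x); dy <- y - mean(y)
  den <- sqrt(sum(dx^2) * sum(dy^2))
  if (den == 0) return(NA_real_)
  sum(dx * dy) / den
}

cor_p_value <- function(r, n) {
  r <- pmin(pmax(r, -1), 1)
  t <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(t), df = n - 2)
  p[abs(r) >= 1] <- 0
  p
}

check_years_aligned <- function(y1, y2) {
  if (!identical(as.integer(y1), as.integer(y2))) {
    off <- union(setdiff(y1, y2), setdiff(y2, y1))
    stop(sprintf("stacks are not aligned: offending years %s",
                 paste(off, collapse = ", ")), call. = FALSE)
  }
}

#' Per-pixel trend or correlation map
#'
#' Applies [theta_slope()] (with its t-based significance) or [pearson_r()]
#' (with the t-based correlation test) to every masked pixel's annual series.
#' A pixel enters the map only if all years are present (missing years are
#' skipped, not imputed).
#'
#' @param agb_stack an [annual_stack()] (e.g. AGB density)
#' @param covariate_stack an [annual_stack()] on the same grid/years, required
#'   for `kind = "correlation"`; ignored for trends
#' @param mask boolean [marsh_raster()]
#' @param kind `"trend"` or `"correlation"`
#' @param variable text label stored with the map
#' @return a `stat_map`: list with `kind`, `variable`, `values` and
#'   `p_values` [marsh_raster()]s
#' @export
pixelwise_map <- function(agb_stack, covariate_stack = NULL, mask,
                          kind = c("trend", "correlation"),
                          variable = "AGB") {
  kind <- match.arg(kind)
  grid <- agb_stack$grid
  if (!grids_equal(grid, mask$grid)) stop_grid_mismatch()
  inside <- !is.na(mask$values) & mask$values > 0.5
  n <- length(agb_stack$years)
  Y <- matrix(agb_stack$values, ncol = n)[inside, , drop = FALSE]
  complete <- rowSums(is.na(Y)) == 0
  vals <- rep(NA_real_, sum(inside))
  pvals <- rep(NA_real_, sum(inside))
  if (kind == "trend") {
    if (any(complete)) {
      st <- slope_stats_matrix(Y[complete, , drop = FALSE])
      vals[complete] <- st$slope
      pvals[complete] <- st$p
    }
  } else {
    if (is.null(covariate_stack))
      stop("correlation maps need a covariate stack", call. = FALSE)
    if (!grids_equal(grid, covariate_stack$grid)) stop_grid_mismatch()
    check_years_aligned(agb_stack$years, covariate_stack$years)
    X <- matrix(covariate_stack$values, ncol = n)[inside, , drop = FALSE]
    complete <- complete & rowSums(is.na(X)) == 0
    if (any(complete)) {
      Yc <- Y[complete, , drop = FALSE]; Xc <- X[complete, , drop = FALSE]
      Yd <- Yc - rowMeans(Yc); Xd <- Xc - rowMeans(Xc)
      den <- sqrt(rowSums(Yd^2) * rowSums(Xd^2))
      r <- ifelse(den > 0, rowSums(Yd * Xd) / den, NA_real_)
      vals[complete] <- r
      pvals[complete] <- ifelse(is.na(r), NA_real_, cor_p_value(r, n))
    }
  }
  vmat <- matrix(NA_real_, grid$nrows, grid$ncols)
  pmat <- matrix(NA_real_, grid$nrows, grid$ncols)
  vmat[inside] <- vals
  pmat[inside] <- pvals
  structure(list(kind = kind, variable = variable,
                 values = marsh_raster(grid, vmat),
                 p_values = marsh_raster(grid, pmat)),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  v <- x$values$values
  cat(sprintf("stat_map (%s, %s): median %.4g, %d pixels, %.1f%% with p < 0.05\n",
              x$kind, x$variable, stats::median(v, na.rm = TRUE),
              sum(!is.na(v)),
              100 * mean(x$p_values$values[!is.na(v)] < 0.05, na.rm = TRUE)))
  invisible(x)
}

#' Regional mean series of an annual stack
#'
#' Per-year mean over the masked, non-missing pixels (the regional average is
#' the average of the corresponding pixels). Years where every masked pixel
#' is missing yield `NA`.
#'
#' @param stack an [annual_stack()]
#' @param mask boolean [marsh_raster()]
#' @return named numeric vector (names = years)
#' @export
regional_series <- function(stack, mask) {
  if (!grids_equal(stack$grid, mask$grid)) stop_grid_mismatch()
  inside <- !is.na(mask$values) & mask$values > 0.5
  if (!any(inside))
    stop("empty region: the mask selects no pixels", call. = FALSE)
  out <- vapply(seq_along(stack$years), function(i) {
    v <- stack$values[, , i][inside]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, numeric(1))
  names(out) <- stack$years
  out
}

#' Correlation table of AGB against monthly/annual climate
#'
#' Correlates the regional AGB series with the regional climate series of each
#' variable for the Annual period and each month, flagging significance at
#' p < 0.05 (`*`) and p < 0.01 (`**`) from the classical t test.
#'
#' @param agb_series regional AGB series (one value per year)
#' @param climate_series named list (by variable) of `periods x years`
#'   matrices, e.g. from [regional_climate_series()]
#' @return a `marsh_cor_table` data frame: `period`, then `r_<var>`,
#'   `p_<var>`, `sig_<var>` per variable
#' @export
correlation_table <- function(agb_series, climate_series) {
  n <- length(agb_series)
  out <- data.frame(period = rownames(climate_series[[1]]),
                    stringsAsFactors = FALSE)
  for (v in names(climate_series)) {
    m <- climate_series[[v]]
    if (ncol(m) != n)
      stop(sprintf("alignment error: climate series for '%s' has %d years, AGB has %d",
                   v, ncol(m), n), call. = FALSE)
    r <- apply(m, 1, function(row) pearson_r(row, agb_series))
    p <- ifelse(is.na(r), NA_real_, cor_p_value(r, n))
    out[[paste0("r_", v)]] <- r
    out[[paste0("p_", v)]] <- p
    out[[paste0("sig_", v)]] <-
      ifelse(is.na(p), "", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
  }
  class(out) <- c("marsh_cor_table", "data.frame")
  out
}

#' @export
print.marsh_cor_table <- function(x, ...) {
  vars <- sub("^r_", "", grep("^r_", names(x), value = TRUE))
  disp <- data.frame(period = x$period)
  for (v in vars)
    disp[[v]] <- paste0(formatC(x[[paste0("r_", v)]], digits = 3,
                                format = "f"), x[[paste0("sig_", v)]])
  print.data.frame(disp, row.names = FALSE)
  invisible(x)
}

#' Split the correlation analysis at a latitude threshold
#'
#' Recomputes the regional AGB series, kriged regional climate series and
#' correlation table separately for the masked pixels south of (<=) and north
#' of (>) the threshold latitude.
#'
#' @param agb_stack AGB [annual_stack()]
#' @param stations long-format station table
#' @param mask boolean [marsh_raster()]
#' @param threshold_deg split latitude in degrees north (default 47)
#' @param variables,periods passed to [regional_climate_series()]
#' @return list with `south` and `north` `marsh_cor_table`s and the two
#'   submasks
#' @export
latitude_split <- function(agb_stack, stations, mask, threshold_deg = 47,
                           variables = CLIMATE_VARS, periods = PERIODS) {
  grid <- agb_stack$grid
  lat <- pixel_latitudes(grid)
  latmat <- matrix(lat, grid$nrows, grid$ncols)
  m <- mask$values
  m[is.na(m)] <- 0
  res <- list()
  for (region in c("south", "north")) {
    sel <- if (region == "south") latmat <= threshold_deg
           else latmat > threshold_deg
    sub <- marsh_raster(grid, (m > 0.5 & sel) * 1)
    if (!any(sub$values > 0.5))
      stop(sprintf("empty region: no masked pixels %s of %g degrees N",
                   region, threshold_deg), call. = FALSE)
    agb <- regional_series(agb_stack, sub)
    clim <- regional_climate_series(stations, grid, sub, agb_stack$years,
                                    variables = variables, periods = periods)
    res[[region]] <- correlation_table(agb, clim)
    res[[paste0(region, "_mask")]] <- sub
  }
  res
}
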