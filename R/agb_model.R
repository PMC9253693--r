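## Calibration of the NDVI_max -> AGB model: quadrat averaging, candidate
## regression forms, selection by R^2 on the data scale, validation metrics,
## raster prediction and regional carbon aggregation.

CARBON_FRACTION <- 0.45   # dry biomass (g/m2) -> carbon (g C/m2)

#' AGB carbon density of a field site
#'
#' Averages the three 1 m x 1 m quadrat dry-biomass values and converts dry
#' mass to carbon with the fixed coefficient 0.45.
#'
#' @param quadrats numeric vector of exactly three non-negative dry-biomass
#'   values, g/m2
#' @return carbon density in g C/m2
#' @export
site_carbon_density <- function(quadrats) {
  if (length(quadrats) != 3)
    stop("a site has exactly three quadrats", call. = FALSE)
  if (any(is.na(quadrats)) || any(quadrats < 0))
    stop("quadrat biomass values must be non-negative", call. = FALSE)
  CARBON_FRACTION * mean(quadrats)
}

#' Add the derived carbon-density column to a sites table
#' @param sites data frame with `quadrat1_g`, `quadrat2_g`, `quadrat3_g`
#' @return `sites` with an `agb_density` column (g C/m2)
#' @export
add_carbon_density <- function(sites) {
  sites$agb_density <- vapply(seq_len(nrow(sites)), function(k)
    site_carbon_density(c(sites$quadrat1_g[k], sites$quadrat2_g[k],
                          sites$quadrat3_g[k])), numeric(1))
  sites
}

MODEL_FORMS <- c("power", "linear", "exponential", "logarithmic")

new_agb_model <- function(form, a, b, ok = TRUE) {
  structure(list(form = form, a = a, b = b, ok = ok,
                 r_squared = NA_real_, rmse = NA_real_,
                 relative_error_pct = NA_real_, n = NA_integer_),
            class = "agb_model")
}

#' Evaluate a calibrated model at NDVI_max values
#' @param object an `agb_model`
#' @param ndvi numeric vector of NDVI_max values
#' @param ... unused
#' @return predicted AGB carbon density, g C/m2
#' @export
predict.agb_model <- function(object, ndvi, ...) {
  if (!isTRUE(object$ok))
    stop("model was not successfully fitted", call. = FALSE)
  switch(object$form,
         power = object$a * ndvi^object$b,
         linear = object$a + object$b * ndvi,
         exponential = object$a * exp(object$b * ndvi),
         logarithmic = ifelse(ndvi > 0, object$a + object$b * log(ndvi),
                              NA_real_),
         stop("unknown model form", call. = FALSE))
}

#' @export
print.agb_model <- function(x, ...) {
  if (!isTRUE(x$ok)) {
    cat(sprintf("agb_model (%s): fit failed\n", x$form))
    return(invisible(x))
  }
  cat(sprintf("agb_model (%s): a = %.4f, b = %.4f, R2 = %.4f, RMSE = %.2f, rel.err = %.2f%% (n = %d)\n",
              x$form, x$a, x$b, x$r_squared, x$rmse, x$relative_error_pct, x$n))
  invisible(x)
}

fit_one_form <- function(form, x, y) {
  fit <- try(switch(form,
    linear = {
      co <- stats::coef(stats::lm(y ~ x))
      new_agb_model("linear", co[[1]], co[[2]])
    },
    logarithmic = {
      co <- stats::coef(stats::lm(y ~ log(x)))
      new_agb_model("logarithmic", co[[1]], co[[2]])
    },
    power = {
      pos <- y > 0
      if (sum(pos) < 3) stop("too few positive responses")
      init <- stats::coef(stats::lm(log(y[pos]) ~ log(x[pos])))
      ft <- minpack.lm::nlsLM(y ~ a * x^b,
                              start = list(a = exp(init[[1]]), b = init[[2]]),
                              control = minpack.lm::nls.lm.control(maxiter = 200))
      co <- stats::coef(ft)
      new_agb_model("power", co[["a"]], co[["b"]])
    },
    exponential = {
      pos <- y > 0
      if (sum(pos) < 3) stop("too few positive responses")
      init <- stats::coef(stats::lm(log(y[pos]) ~ x[pos]))
      ft <- minpack.lm::nlsLM(y ~ a * exp(b * x),
                              start = list(a = exp(init[[1]]), b = init[[2]]),
                              control = minpack.lm::nls.lm.control(maxiter = 200))
      co <- stats::coef(ft)
      new_agb_model("exponential", co[["a"]], co[["b"]])
    }), silent = TRUE)
  if (inherits(fit, "try-error") || !is.finite(fit$a) || !is.finite(fit$b))
    return(new_agb_model(form, NA_real_, NA_real_, ok = FALSE))
  fit
}

#' Fit all candidate NDVI_max -> AGB regression forms
#'
#' Fits power (`a * x^b`), linear, exponential and logarithmic models to the
#' paired (NDVI_max, AGB carbon density) data. The power and exponential forms
#' are fitted by nonlinear least squares on the original AGB scale,
#' initialised from the log-transformed ordinary least-squares fit, so that
#' the reported R^2 (computed as `1 - SS_res/SS_tot` on the untransformed
#' scale) describes the fit actually used for prediction. Degenerate inputs
#' (e.g. constant NDVI) flag the affected forms as failed rather than raising.
#'
#' @param pairs data frame with columns `ndvi_max` (> 0) and `agb_density`
#' @return named list of `agb_model` objects, one per candidate form
#' @export
fit_candidates <- function(pairs) {
  x <- pairs$ndvi_max; y <- pairs$agb_density
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3)
    stop("need at least 3 (ndvi_max, agb_density) pairs", call. = FALSE)
  if (any(x <= 0))
    stop("ndvi_max values must be positive for calibration", call. = FALSE)
  models <- lapply(MODEL_FORMS, function(fm) {
    m <- if (stats::sd(x) == 0) new_agb_model(fm, NA_real_, NA_real_, ok = FALSE)
         else fit_one_form(fm, x, y)
    if (isTRUE(m$ok)) {
      est <- predict(m, x)
      ok_est <- is.finite(est)
      ss_res <- sum((y[ok_est] - est[ok_est])^2)
      ss_tot <- sum((y[ok_est] - mean(y[ok_est]))^2)
      m$r_squared <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
      v <- validate_model(m, data.frame(ndvi_max = x, agb_density = y))
      m$rmse <- v$rmse
      m$relative_error_pct <- v$relative_error_pct
      m$n <- length(x)
    }
    m
  })
  names(models) <- MODEL_FORMS
  models
}

#' Select the best calibrated model by R^2
#'
#' Returns the successfully fitted model with the largest R^2 (computed on the
#' original AGB scale). Ties break toward fewer parameters, then toward the
#' earlier form in the order power, linear, exponential, logarithmic.
#'
#' @param models list of `agb_model` objects (e.g. from [fit_candidates()])
#' @return the selected `agb_model`
#' @export
select_best <- function(models) {
  ok <- Filter(function(m) isTRUE(m$ok) && is.finite(m$r_squared), models)
  if (!length(ok))
    stop("model selection failed: no candidate fitted successfully",
         call. = FALSE)
  npar <- vapply(ok, function(m) 2L, integer(1))  # all candidate forms have 2
  r2 <- vapply(ok, function(m) m$r_squared, numeric(1))
  ord <- match(vapply(ok, function(m) m$form, character(1)), MODEL_FORMS)
  best <- order(-r2, npar, ord)[1]
  ok[[best]]
}

#' Validate a model against observed pairs
#'
#' RMSE is the root mean squared residual over the n samples; relative error
#' is 100 x the mean of per-sample `|obs - est| / obs`. Samples with observed
#' AGB of exactly zero are excluded from the relative error (with a warning)
#' since their per-sample ratio is undefined.
#'
#' @param model an `agb_model`
#' @param pairs data frame with `ndvi_max` and `agb_density`
#' @return list with `rmse` (g C/m2) and `relative_error_pct`
#' @export
validate_model <- function(model, pairs) {
  if (nrow(pairs) < 1) stop("need at least one pair", call. = FALSE)
  obs <- pairs$agb_density
  est <- predict(model, pairs$ndvi_max)
  rmse <- sqrt(mean((obs - est)^2))
  nz <- obs != 0
  if (any(!nz))
    warning(sprintf("%d sample(s) with observed AGB = 0 excluded from relative error",
                    sum(!nz)))
  rel <- if (any(nz)) 100 * mean(abs(obs[nz] - est[nz]) / obs[nz]) else NA_real_
  list(rmse = rmse, relative_error_pct = rel)
}

#' Predict an AGB carbon-density raster from NDVI_max
#'
#' Applies the calibrated model per pixel inside the stable marsh mask. NDVI
#' is clipped to [0, 1] before evaluation; pixels outside the mask or with
#' missing NDVI are missing in the output.
#'
#' @param model a fitted `agb_model`
#' @param ndvi_max a [marsh_raster()] of annual NDVI_max
#' @param mask a boolean [marsh_raster()] on the same grid
#' @return a [marsh_raster()] of AGB carbon density, g C/m2
#' @export
predict_raster <- function(model, ndvi_max, mask) {
  if (!isTRUE(model$ok))
    stop("model was not successfully fitted", call. = FALSE)
  if (!grids_equal(ndvi_max$grid, mask$grid)) stop_grid_mismatch()
  x <- pmin(pmax(ndvi_max$values, 0), 1)
  out <- predict(model, x)
  out[is.na(ndvi_max$values)] <- NA_real_
  m <- mask$values
  out[is.na(m) | m < 0.5] <- NA_real_
  marsh_raster(ndvi_max$grid, out)
}

#' Predict the AGB stack for every year
#' @param model a fitted `agb_model`
#' @param ndvi_stack an [annual_stack()] of NDVI_max
#' @param mask a boolean [marsh_raster()]
#' @return an [annual_stack()] of AGB carbon density
#' @export
predict_agb_stack <- function(model, ndvi_stack, mask) {
  out <- array(NA_real_, dim(ndvi_stack$values))
  for (i in seq_along(ndvi_stack$years))
    out[, , i] <- predict_raster(model, stack_layer(ndvi_stack,
                                                    ndvi_stack$years[i]),
                                 mask)$values
  annual_stack(ndvi_stack$grid, ndvi_stack$years, out)
}

#' Regional mean density, area and total carbon stock
#'
#' Mean AGB carbon density over the non-missing masked pixels, the masked
#' area (pixel count times pixel area), and the regional total carbon stock
#' `mean_density x area x 1e-12` in teragrams of carbon.
#'
#' @param agb a [marsh_raster()] of AGB carbon density (g C/m2)
#' @param mask a boolean [marsh_raster()] on the same grid
#' @return list with `mean_density` (g C/m2), `area_m2`, `total_TgC`,
#'   `n_pixels`
#' @export
regional_summary <- function(agb, mask) {
  if (!grids_equal(agb$grid, mask$grid)) stop_grid_mismatch()
  m <- mask$values
  inside <- !is.na(m) & m > 0.5
  if (!any(inside))
    stop("empty region: the mask selects no pixels", call. = FALSE)
  v <- agb$values[inside]
  v <- v[!is.na(v)]
  if (!length(v))
    stop("empty region: all masked pixels are missing", call. = FALSE)
  area <- sum(inside) * agb$grid$pixel_size^2
  mean_density <- mean(v)
  list(mean_density = mean_density, area_m2 = area,
       total_TgC = mean_density * area * 1e-12, n_pixels = sum(inside))
}
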