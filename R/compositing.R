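## Stable marsh mask, maximum value compositing (MVC) and site-pixel pairing.

#' Stable marsh mask from two epoch extent maps
#'
#' A pixel is marsh in the stable mask exactly when both epoch maps flag it as
#' marsh; intersecting the two epochs removes areas converted between the
#' epochs (e.g. by drainage or reclamation). Missing cells count as non-marsh.
#'
#' @param mask_t1,mask_t2 boolean [marsh_raster()]s (values 1/0/NA) on one grid
#' @return a boolean [marsh_raster()]
#' @export
stable_marsh_mask <- function(mask_t1, mask_t2) {
  if (!grids_equal(mask_t1$grid, mask_t2$grid)) stop_grid_mismatch()
  a <- mask_t1$values; b <- mask_t2$values
  a[is.na(a)] <- 0; b[is.na(b)] <- 0
  marsh_raster(mask_t1$grid, ((a > 0.5) & (b > 0.5)) * 1)
}

#' Annual maximum-value composite of NDVI
#'
#' Reduces the within-year stack of NDVI composites to the per-pixel maximum,
#' the standard MVC step that suppresses cloud and atmospheric artefacts.
#' Missing composites are ignored; a pixel is missing only when it is missing
#' in every composite.
#'
#' @param composites list of [marsh_raster()]s on one grid (>= 1)
#' @param year optional calendar year label attached to the result
#' @return a [marsh_raster()] of annual NDVI_max
#' @export
annual_ndvi_max <- function(composites, year = NULL) {
  if (length(composites) < 1)
    stop("annual_ndvi_max needs at least one composite", call. = FALSE)
  grid <- composites[[1]]$grid
  for (r in composites)
    if (!grids_equal(r$grid, grid)) stop_grid_mismatch()
  out <- composites[[1]]$values
  for (r in composites[-1]) out <- pmax(out, r$values, na.rm = TRUE)
  res <- marsh_raster(grid, out)
  attr(res, "year") <- year
  res
}

#' Build the annual NDVI_max stack from a scene's composite array
#'
#' @param scene a [generate_scene()] result (or any list with `grid` and a
#'   4-D `ndvi_series` array plus `config$years`)
#' @return an [annual_stack()] of NDVI_max, one layer per year
#' @export
scene_ndvi_max_stack <- function(scene) {
  dims <- dim(scene$ndvi_series)
  ny <- dims[4]
  out <- array(0, c(dims[1], dims[2], ny))
  for (i in seq_len(ny)) {
    m <- scene$ndvi_series[, , 1, i]
    for (j in seq_len(dims[3])[-1])
      m <- pmax(m, scene$ndvi_series[, , j, i], na.rm = TRUE)
    out[, , i] <- m
  }
  annual_stack(scene$grid, scene$config$years, out)
}

#' NDVI_max at a field site's location and year
#'
#' Looks up the pixel containing the site in the given year's layer, using the
#' nearest-pixel-centre rule at boundaries (ties toward smaller row, then
#' smaller column). A missing pixel returns `NA` (a missing-value signal,
#' distinct from the error raised for a point outside the grid extent).
#'
#' @param stack an [annual_stack()] of NDVI_max
#' @param x,y site coordinates: projected metres, or lon/lat degrees with
#'   `lonlat = TRUE`
#' @param year the sample's calendar year (must be in the stack)
#' @param lonlat interpret `x`, `y` as lon/lat and project via the grid CRS
#' @return NDVI_max value (dimensionless), `NA` if the pixel is missing
#' @export
site_ndvi_max <- function(stack, x, y, year, lonlat = FALSE) {
  i <- match(year, stack$years)
  if (is.na(i)) stop(sprintf("year %d not in stack", year), call. = FALSE)
  if (lonlat) {
    xy <- lonlat_to_xy(stack$grid, x, y)
    x <- xy$x; y <- xy$y
  }
  rc <- xy_nearest_pixel(stack$grid, x, y)
  stack$values[rc$row, rc$col, i]
}

#' Pair field sites with their pixel NDVI_max
#'
#' Adds an `ndvi_max` column to a sites table by looking up each sample's own
#' year's NDVI_max layer at the site position.
#'
#' @param sites data frame with `lon`, `lat`, `year` (schema of
#'   [generate_scene()] sites)
#' @param stack an [annual_stack()] of NDVI_max
#' @return `sites` with an `ndvi_max` column appended
#' @export
pair_sites_ndvi <- function(sites, stack) {
  sites$ndvi_max <- vapply(seq_len(nrow(sites)), function(k)
    site_ndvi_max(stack, sites$lon[k], sites$lat[k], sites$year[k],
                  lonlat = TRUE), numeric(1))
  sites
}
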