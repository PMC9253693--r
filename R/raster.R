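#' Raster grid geometry
#'
#' A `raster_grid` describes a regular, axis-aligned grid in projected metres:
#' its dimensions, the projected coordinate of the top-left corner, the square
#' pixel size, and a text CRS label. Row/column indices are 1-based; pixel
#' (r, c) covers the half-open square
#' `[x0 + (c-1)s, x0 + c s) x (y0 - r s, y0 - (r-1) s]`
#' where `(x0, y0)` is the top-left corner and `s` the pixel size. This makes
#' point-in-pixel tests unambiguous at pixel edges.
#'
#' The CRS label `"local:lon0=<deg>,lat0=<deg>"` denotes a local equirectangular
#' projection about a reference point: `x = (lon - lon0) * 111320 * cos(lat0)`,
#' `y = (lat - lat0) * 111320`. It is the georeferencing used by the synthetic
#' scenes and is sufficient to compute per-pixel latitude for regional splits.
#'
#' @param nrows,ncols grid dimensions (>= 1)
#' @param origin_x,origin_y projected coordinates of the top-left corner (m)
#' @param pixel_size pixel edge length in metres (> 0)
#' @param crs_id text CRS label
#' @return an object of class `raster_grid`
#' @export
raster_grid <- function(nrows, ncols, origin_x, origin_y, pixel_size,
                        crs_id = "local:lon0=133,lat0=47") {
  stopifnot(nrows >= 1, ncols >= 1, pixel_size > 0)
  structure(list(nrows = as.integer(nrows), ncols = as.integer(ncols),
                 origin_x = origin_x, origin_y = origin_y,
                 pixel_size = pixel_size, crs_id = crs_id),
            class = "raster_grid")
}

#' @export
print.raster_grid <- function(x, ...) {
  cat(sprintf("raster_grid: %d x %d pixels of %g m, origin (%g, %g), crs '%s'\n",
              x$nrows, x$ncols, x$pixel_size, x$origin_x, x$origin_y, x$crs_id))
  invisible(x)
}

grids_equal <- function(g1, g2) {
  isTRUE(all.equal(unclass(g1)[c("nrows", "ncols", "origin_x", "origin_y",
                                 "pixel_size")],
                   unclass(g2)[c("nrows", "ncols", "origin_x", "origin_y",
                                 "pixel_size")]))
}

stop_grid_mismatch <- function() {
  stop("incompatible grids: rasters do not share one grid",
       call. = FALSE)
}

#' Georeferenced raster layer
#'
#' A `marsh_raster` couples a [raster_grid()] with a numeric matrix of values
#' (`nrows` x `ncols`, row 1 = northernmost). `NA` is the missing-data marker
#' and is never compared as a number.
#'
#' @param grid a [raster_grid()]
#' @param values numeric or logical matrix matching the grid dimensions, or a
#'   single value to fill the grid with
#' @return an object of class `marsh_raster`
#' @export
marsh_raster <- function(grid, values) {
  stopifnot(inherits(grid, "raster_grid"))
  if (length(values) == 1L)
    values <- matrix(as.numeric(values), grid$nrows, grid$ncols)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) != grid$nrows || ncol(values) != grid$ncols)
    stop("values matrix shape does not match grid", call. = FALSE)
  structure(list(grid = grid, values = values), class = "marsh_raster")
}

#' @export
print.marsh_raster <- function(x, ...) {
  v <- x$values
  cat(sprintf("marsh_raster: %d x %d, range [%s, %s], %d missing\n",
              x$grid$nrows, x$grid$ncols,
              format(suppressWarnings(min(v, na.rm = TRUE))),
              format(suppressWarnings(max(v, na.rm = TRUE))),
              sum(is.na(v))))
  invisible(x)
}

#' Annual raster stack
#'
#' Ordered multi-year collection of co-registered layers sharing one grid,
#' holding e.g. annual maximum NDVI or predicted AGB density.
#'
#' @param grid a [raster_grid()]
#' @param years strictly increasing integer vector
#' @param values 3-D array `nrows x ncols x length(years)`
#' @return an object of class `annual_stack`
#' @export
annual_stack <- function(grid, years, values) {
  stopifnot(inherits(grid, "raster_grid"))
  years <- as.integer(years)
  if (length(years) > 1 && any(diff(years) <= 0))
    stop("years must be strictly increasing", call. = FALSE)
  values <- as.array(values)
  if (length(dim(values)) != 3 ||
      !all(dim(values) == c(grid$nrows, grid$ncols, length(years))))
    stop("stack array must be nrows x ncols x n_years", call. = FALSE)
  structure(list(grid = grid, years = years, values = values),
            class = "annual_stack")
}

#' Extract one year's layer from a stack
#' @param stack an [annual_stack()]
#' @param year calendar year present in the stack
#' @return a [marsh_raster()]
#' @export
stack_layer <- function(stack, year) {
  i <- match(year, stack$years)
  if (is.na(i)) stop(sprintf("year %d not in stack", year), call. = FALSE)
  marsh_raster(stack$grid, stack$values[, , i, drop = TRUE])
}

## ---- coordinate math -------------------------------------------------------

#' Convert projected coordinates to row/column indices
#'
#' Uses the half-open pixel convention: a point on a pixel's left or top edge
#' belongs to that pixel. Points outside the grid extent give `NA`.
#'
#' @param grid a [raster_grid()]
#' @param x,y projected coordinates (m), vectorised
#' @return list with integer vectors `row`, `col` (`NA` outside extent)
#' @export
xy_to_rowcol <- function(grid, x, y) {
  s <- grid$pixel_size
  col <- floor((x - grid$origin_x) / s) + 1
  row <- floor((grid$origin_y - y) / s) + 1
  bad <- col < 1 | col > grid$ncols | row < 1 | row > grid$nrows
  col[bad] <- NA_integer_
  row[bad] <- NA_integer_
  list(row = as.integer(row), col = as.integer(col))
}

#' Row/column of the pixel whose centre is nearest a point
#'
#' Boundary rule for site-to-pixel pairing: a point equidistant from several
#' pixel centres (i.e. lying on a shared pixel edge or corner) resolves to the
#' smaller row index, then the smaller column index.
#'
#' @inheritParams xy_to_rowcol
#' @return list with integer vectors `row`, `col`
#' @export
xy_nearest_pixel <- function(grid, x, y) {
  s <- grid$pixel_size
  u <- (grid$origin_y - y) / s   # row-axis position, row r centre at r - 0.5
  v <- (x - grid$origin_x) / s   # col-axis position, col c centre at c - 0.5
  inside <- v >= 0 & v <= grid$ncols & u >= 0 & u <= grid$nrows
  if (any(!inside))
    stop("point outside grid extent", call. = FALSE)
  # ceiling() rounds half-distances down, implementing the smaller-index tie rule
  row <- pmin(pmax(ceiling(u), 1L), grid$nrows)
  col <- pmin(pmax(ceiling(v), 1L), grid$ncols)
  list(row = as.integer(row), col = as.integer(col))
}

#' Projected coordinates of pixel centres
#' @param grid a [raster_grid()]
#' @param row,col 1-based indices (vectorised)
#' @return list with numeric vectors `x`, `y`
#' @export
rowcol_to_xy <- function(grid, row, col) {
  s <- grid$pixel_size
  list(x = grid$origin_x + (col - 0.5) * s,
       y = grid$origin_y - (row - 0.5) * s)
}

M_PER_DEG <- 111320

crs_local_params <- function(crs_id) {
  m <- regmatches(crs_id,
                  regexec("^local:lon0=([-0-9.]+),lat0=([-0-9.]+)$", crs_id))[[1]]
  if (length(m) != 3) return(NULL)
  list(lon0 = as.numeric(m[2]), lat0 = as.numeric(m[3]))
}

#' Project lon/lat to grid coordinates, and back
#'
#' Only `local:` CRS labels are supported; anything else raises an error,
#' since the package does no reprojection between reference systems.
#'
#' @param grid a [raster_grid()]
#' @param lon,lat geographic coordinates in decimal degrees
#' @return list with `x`, `y` in projected metres
#' @export
lonlat_to_xy <- function(grid, lon, lat) {
  p <- crs_local_params(grid$crs_id)
  if (is.null(p))
    stop(sprintf("crs '%s' does not support lon/lat conversion", grid$crs_id),
         call. = FALSE)
  list(x = (lon - p$lon0) * M_PER_DEG * cos(p$lat0 * pi / 180),
       y = (lat - p$lat0) * M_PER_DEG)
}

#' @rdname lonlat_to_xy
#' @param x,y projected coordinates in metres
#' @export
xy_to_lonlat <- function(grid, x, y) {
  p <- crs_local_params(grid$crs_id)
  if (is.null(p))
    stop(sprintf("crs '%s' does not support lon/lat conversion", grid$crs_id),
         call. = FALSE)
  list(lon = p$lon0 + x / (M_PER_DEG * cos(p$lat0 * pi / 180)),
       lat = p$lat0 + y / M_PER_DEG)
}

#' Latitude of each pixel row
#' @param grid a [raster_grid()]
#' @return numeric vector of length `nrows`: latitude of each row's pixel centres
#' @export
pixel_latitudes <- function(grid) {
  xy <- rowcol_to_xy(grid, seq_len(grid$nrows), 1)
  xy_to_lonlat(grid, xy$x, xy$y)$lat
}

## ---- resampling ------------------------------------------------------------

#' Resample a boolean mask to a coarser grid by majority rule
#'
#' Each source pixel centre votes in the target pixel containing it; a target
#' pixel is true when at least half of its non-missing votes are true, missing
#' when it receives no votes or only missing votes. Used to bring a fine marsh
#' extent map (e.g. 30 m) onto the NDVI analysis grid (e.g. 250 m) before the
#' two epoch maps are intersected.
#'
#' @param mask a boolean [marsh_raster()] (values 0/1/NA)
#' @param target_grid the coarser [raster_grid()]
#' @return a boolean [marsh_raster()] on `target_grid`
#' @export
resample_mask_majority <- function(mask, target_grid) {
  g <- mask$grid
  rc <- expand.grid(row = seq_len(g$nrows), col = seq_len(g$ncols))
  xy <- rowcol_to_xy(g, rc$row, rc$col)
  trc <- xy_to_rowcol(target_grid, xy$x, xy$y)
  v <- as.vector(mask$values[cbind(rc$row, rc$col)])
  keep <- !is.na(trc$row) & !is.na(v)
  idx <- (trc$col[keep] - 1L) * target_grid$nrows + trc$row[keep]
  ones <- tapply(v[keep], idx, sum)
  n <- tapply(v[keep], idx, length)
  out <- matrix(NA_real_, target_grid$nrows, target_grid$ncols)
  out[as.integer(names(ones))] <- as.numeric(ones / n >= 0.5)
  marsh_raster(target_grid, out)
}

## ---- text raster I/O (ESRI ASCII grid) -------------------------------------

#' Write a raster as an ESRI ASCII grid
#'
#' Plain-text interchange format: a six-line header (ncols, nrows, xllcorner,
#' yllcorner, cellsize, NODATA_value) followed by rows north to south. Mask
#' rasters are written with values 1/0 and missing cells as the nodata marker.
#'
#' @param raster a [marsh_raster()]
#' @param path output file path (conventionally `.asc`)
#' @param nodata numeric nodata marker
#' @export
write_asc <- function(raster, path, nodata = -9999) {
  g <- raster$grid
  hdr <- c(sprintf("ncols %d", g$ncols),
           sprintf("nrows %d", g$nrows),
           sprintf("xllcorner %.10g", g$origin_x),
           sprintf("yllcorner %.10g", g$origin_y - g$nrows * g$pixel_size),
           sprintf("cellsize %.10g", g$pixel_size),
           sprintf("NODATA_value %g", nodata))
  v <- raster$values
  v[is.na(v)] <- nodata
  body <- apply(v, 1, function(r) paste(format(r, trim = TRUE, digits = 10),
                                        collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read an ESRI ASCII grid
#' @param path file path
#' @param crs_id CRS label to attach (the format itself carries none)
#' @return a [marsh_raster()]
#' @export
read_asc <- function(path, crs_id = "local:lon0=133,lat0=47") {
  lines <- readLines(path)
  hdr <- lines[1:6]
  val <- function(key) {
    ln <- hdr[grepl(paste0("^", key, "\\b"), hdr, ignore.case = TRUE)]
    as.numeric(strsplit(trimws(ln), "\\s+")[[1]][2])
  }
  ncols <- val("ncols"); nrows <- val("nrows")
  cell <- val("cellsize"); nodata <- val("NODATA_value")
  xll <- val("xllcorner"); yll <- val("yllcorner")
  body <- strsplit(trimws(lines[-(1:6)]), "\\s+")
  v <- do.call(rbind, lapply(body, as.numeric))
  v[v == nodata] <- NA_real_
  grid <- raster_grid(nrows, ncols, origin_x = xll,
                      origin_y = yll + nrows * cell, pixel_size = cell,
                      crs_id = crs_id)
  marsh_raster(grid, v)
}
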