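## End-to-end orchestration: simulate or load inputs, derive the stable mask
## and NDVI_max stack, calibrate/select/validate the biomass model, predict
## the AGB stack, and run the trend and climate-correlation analyses. All
## outputs are plain-text files (ASCII grids, CSV, JSON).

#' Run configuration
#'
#' Exactly one of `scene` (a [scene_config()] for simulation) or `input_dir`
#' (a directory written by [write_scene()] holding real-format inputs) must be
#' given.
#'
#' @param scene a [scene_config()], or `NULL`
#' @param input_dir directory with `mask_epoch1.asc`, `mask_epoch2.asc`,
#'   `ndvi/ndvi_<year>_<cc>.asc`, `stations.csv`, `sites.csv`, or `NULL`
#' @param out_dir output directory
#' @param lat_threshold latitude (deg N) for the regional split
#' @param correlation_periods periods for the correlation table (default
#'   Annual + all 12 months)
#' @param map_periods periods for which pixel-wise climate correlation maps
#'   are produced (default Annual only; each period adds one kriged surface
#'   per variable and year)
#' @param run_latitude_split compute the south/north split tables
#' @param seed seed for any stochastic step (scene simulation, jitter retries)
#' @param verbose log stage progress to stderr
#' @return an object of class `run_config`
#' @export
run_config <- function(scene = NULL, input_dir = NULL, out_dir = tempfile("marshagb_"),
                       lat_threshold = 47, correlation_periods = PERIODS,
                       map_periods = "Annual", run_latitude_split = TRUE,
                       seed = 1, verbose = TRUE) {
  if (is.null(scene) == is.null(input_dir))
    stop("exactly one of 'scene' (simulation) or 'input_dir' must be given",
         call. = FALSE)
  structure(list(scene = scene, input_dir = input_dir, out_dir = out_dir,
                 lat_threshold = lat_threshold,
                 correlation_periods = correlation_periods,
                 map_periods = map_periods,
                 run_latitude_split = run_latitude_split,
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "run_config")
}

#' Load a run configuration from a YAML or JSON file
#' @param path file path (`.yml`/`.yaml` or `.json`)
#' @return a `run_config`
#' @export
read_run_config <- function(path) {
  lst <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  if (!is.null(lst$scene)) lst$scene <- do.call(scene_config, lst$scene)
  do.call(run_config, lst)
}

#' Read scene-format inputs from disk
#' @param dir directory written by [write_scene()]
#' @return list with `mask_epoch1`, `mask_epoch2`, `ndvi_series`, `stations`,
#'   `sites`, `grid`, `config` (years/composites only)
#' @export
read_scene_inputs <- function(dir) {
  tr <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  crs <- tr$crs_id
  m1 <- read_asc(file.path(dir, "mask_epoch1.asc"), crs_id = crs)
  m2 <- read_asc(file.path(dir, "mask_epoch2.asc"), crs_id = crs)
  years <- as.integer(tr$years)
  ncomp <- as.integer(tr$composites_per_year)
  g <- m1$grid
  ndvi <- array(NA_real_, c(g$nrows, g$ncols, ncomp, length(years)))
  for (i in seq_along(years))
    for (j in seq_len(ncomp))
      ndvi[, , j, i] <- read_asc(file.path(dir, "ndvi",
                                           sprintf("ndvi_%d_%02d.asc",
                                                   years[i], j)),
                                 crs_id = crs)$values
  list(mask_epoch1 = m1, mask_epoch2 = m2, ndvi_series = ndvi,
       stations = utils::read.csv(file.path(dir, "stations.csv")),
       sites = utils::read.csv(file.path(dir, "sites.csv")),
       grid = g,
       config = list(years = years, composites_per_year = ncomp))
}

log_stage <- function(cfg, fmt, ...) {
  if (cfg$verbose) message(sprintf("[marshAGB] %s", sprintf(fmt, ...)))
}

run_stage <- function(cfg, stage, expr) {
  log_stage(cfg, "stage %s ...", stage)
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE))
  log_stage(cfg, "stage %s done (%.1f s)", stage,
            proc.time()[["elapsed"]] - t0)
  res
}

#' Run the full analysis pipeline
#'
#' Stages: load/simulate inputs; intersect the two epoch masks into the stable
#' marsh mask; composite 16-day NDVI to annual NDVI_max; pair field sites with
#' their pixel NDVI_max; fit and select the calibration model; predict the
#' annual AGB stack; summarise regional density/area/total carbon; map
#' per-pixel AGB trends; krige station climate and build the Annual+monthly
#' correlation table (and, optionally, the south/north latitude split and
#' pixel-wise climate correlation maps). Outputs are written under
#' `config$out_dir`; the machine-readable summary goes to `summary.json`.
#' Runs are deterministic for a fixed configuration and seed.
#'
#' @param config a [run_config()]
#' @return the summary as a list (invisibly returns files on disk); the
#'   summary is also written to `<out_dir>/summary.json`
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  inputs <- run_stage(config, "inputs", {
    if (!is.null(config$scene)) {
      cfg <- config$scene
      cfg$seed <- cfg$seed + config$seed  # one stream per (scene, run) pair
      generate_scene(cfg)
    } else read_scene_inputs(config$input_dir)
  })
  grid <- inputs$grid
  years <- inputs$config$years

  mask <- run_stage(config, "mask",
                    stable_marsh_mask(inputs$mask_epoch1, inputs$mask_epoch2))
  write_asc(mask, file.path(config$out_dir, "stable_mask.asc"))

  ndvi_stack <- run_stage(config, "composite", scene_ndvi_max_stack(inputs))

  sites <- run_stage(config, "pair", {
    s <- add_carbon_density(inputs$sites)
    pair_sites_ndvi(s, ndvi_stack)
  })
  utils::write.csv(sites, file.path(config$out_dir, "sites_paired.csv"),
                   row.names = FALSE)

  model <- run_stage(config, "fit", {
    cand <- fit_candidates(sites)
    best <- select_best(cand)
    jsonlite::write_json(
      list(selected = unclass(best),
           candidates = lapply(cand, unclass)),
      file.path(config$out_dir, "model.json"), auto_unbox = TRUE, digits = NA)
    best
  })

  agb_stack <- run_stage(config, "predict",
                         predict_agb_stack(model, ndvi_stack, mask))
  agb_mean <- marsh_raster(grid, apply(agb_stack$values, c(1, 2), mean))
  write_asc(agb_mean, file.path(config$out_dir, "agb_mean.asc"))

  summary_reg <- run_stage(config, "summarise", regional_summary(agb_mean, mask))

  trend_map <- run_stage(config, "trend",
                         pixelwise_map(agb_stack, mask = mask, kind = "trend"))
  write_asc(trend_map$values, file.path(config$out_dir, "agb_trend.asc"))
  write_asc(trend_map$p_values, file.path(config$out_dir, "agb_trend_p.asc"))
  agb_series <- regional_series(agb_stack, mask)
  regional_trend <- theta_slope(agb_series)
  regional_trend_p <- slope_significance(agb_series)

  clim <- run_stage(config, "correlate", {
    regional_climate_series(inputs$stations, grid, mask, years,
                            periods = config$correlation_periods)
  })
  cor_tab <- correlation_table(agb_series, clim)
  utils::write.csv(as.data.frame(cor_tab),
                   file.path(config$out_dir, "correlation_table.csv"),
                   row.names = FALSE)

  cor_maps <- run_stage(config, "correlation-maps", {
    maps <- list()
    for (p in config$map_periods)
      for (v in CLIMATE_VARS) {
        arr <- array(NA_real_, c(grid$nrows, grid$ncols, length(years)))
        for (i in seq_along(years))
          arr[, , i] <- krige_climate(inputs$stations, grid, years[i], p,
                                      v)$surface$values
        cov_stack <- annual_stack(grid, years, arr)
        sm <- pixelwise_map(agb_stack, cov_stack, mask, "correlation",
                            variable = sprintf("%s-%s", v, p))
        write_asc(sm$values,
                  file.path(config$out_dir, sprintf("cor_%s_%s.asc", v, p)))
        maps[[sprintf("%s-%s", v, p)]] <- sm
      }
    maps
  })

  split <- if (config$run_latitude_split)
    run_stage(config, "latitude-split",
              latitude_split(agb_stack, inputs$stations, mask,
                             threshold_deg = config$lat_threshold,
                             periods = config$correlation_periods))
  else NULL

  summary <- list(
    n_sites = nrow(sites), n_years = length(years), years = years,
    model = list(form = model$form, a = model$a, b = model$b,
                 r_squared = model$r_squared, rmse = model$rmse,
                 relative_error_pct = model$relative_error_pct),
    regional = summary_reg,
    regional_trend = list(slope = regional_trend, p = regional_trend_p),
    trend_map_median = stats::median(trend_map$values$values, na.rm = TRUE),
    correlation_table = as.data.frame(cor_tab))
  if (!is.null(split))
    summary$latitude_split <- list(
      threshold_deg = config$lat_threshold,
      south = as.data.frame(split$south), north = as.data.frame(split$north))
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  log_stage(config, "run complete: outputs in %s", config$out_dir)
  invisible(structure(list(summary = summary, out_dir = config$out_dir,
                           model = model, mask = mask, agb_stack = agb_stack,
                           trend_map = trend_map, correlation_table = cor_tab,
                           cor_maps = cor_maps, latitude_split = split,
                           sites = sites),
                      class = "run_report"))
}
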