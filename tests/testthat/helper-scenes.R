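# Shared fixtures: small scenes are generated once per test run and cached,
# so individual tests stay fast while exercising the full generator.

.scene_cache <- new.env(parent = emptyenv())

cached_scene <- function(key, cfg) {
  if (is.null(.scene_cache[[key]]))
    .scene_cache[[key]] <- generate_scene(cfg)
  .scene_cache[[key]]
}

small_cfg <- function(seed = 11, ...) {
  scene_config(nrows = 24, ncols = 24, years = 2000:2020, seed = seed, ...)
}

small_scene <- function() cached_scene("small", small_cfg())

noise_free_scene <- function() {
  cached_scene("noise_free",
               small_cfg(ndvi_noise_sd = 0, agb_noise_cv = 0,
                         july_tmean_effect = 0))
}

# grid of unit pixels with origin at (0, n): row r, col c pixel centre at
# (c - 0.5, n - r + 0.5); convenient for hand-computed coordinate checks
unit_grid <- function(n = 10) raster_grid(n, n, 0, n, 1)

random_mask <- function(grid, p = 0.5) {
  marsh_raster(grid, matrix(rbinom(grid$nrows * grid$ncols, 1, p),
                            grid$nrows, grid$ncols))
}
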