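#!/usr/bin/env Rscript
# Thin command-line wrapper around marshAGB::run_pipeline(). Usage:
#   Rscript scripts/run_pipeline.R --config run.yml [--out-dir DIR] [--seed N] [--quiet]
# The config file (YAML or JSON) follows marshAGB::read_run_config(); with no
# --config a default simulated scene is analysed.

suppressPackageStartupMessages({
  library(optparse)
  library(marshAGB)
})

parser <- OptionParser(option_list = list(
  make_option("--config", type = "character", default = NULL,
              help = "YAML/JSON run configuration"),
  make_option("--out-dir", dest = "out_dir", type = "character", default = NULL,
              help = "override the output directory"),
  make_option("--seed", type = "integer", default = NULL,
              help = "override the run seed"),
  make_option("--quiet", action = "store_true", default = FALSE,
              help = "suppress stage logging")
))
opt <- parse_args(parser)

cfg <- if (!is.null(opt$config)) {
  read_run_config(opt$config)
} else {
  run_config(scene = scene_config(), out_dir = "marshagb_run")
}
if (!is.null(opt$out_dir)) cfg$out_dir <- opt$out_dir
if (!is.null(opt$seed)) cfg$seed <- opt$seed
if (opt$quiet) cfg$verbose <- FALSE

rep <- run_pipeline(cfg)
s <- rep$summary
cat(sprintf("model: %s, a = %.2f, b = %.4f (R2 = %.3f)\n",
            s$model$form, s$model$a, s$model$b, s$model$r_squared))
cat(sprintf("regional mean density %.2f g C/m2 over %.3g m2 -> %.4g Tg C\n",
            s$regional$mean_density, s$regional$area_m2, s$regional$total_TgC))
cat(sprintf("regional AGB trend %.3f g C/m2/a (p = %.3g)\n",
            s$regional_trend$slope, s$regional_trend$p))
cat(sprintf("outputs in %s\n", cfg$out_dir))
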