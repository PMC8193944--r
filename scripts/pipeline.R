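#!/usr/bin/env Rscript
# Thin command-line entry point over the package's pipeline functions.
#
#   Rscript scripts/pipeline.R run-all   [--config cfg.yaml] [--out DIR]
#   Rscript scripts/pipeline.R <stage>   [--config cfg.yaml] [--out DIR]
#       with <stage> one of: detect quantal dose-fit fura circadian anova
#   Rscript scripts/pipeline.R make-fixtures [--out DIR] [--seed N]

suppressPackageStartupMessages({
  library(optparse)
  library(synphys)
})

args <- commandArgs(trailingOnly = TRUE)
if (!length(args)) stop("no subcommand given; see the header of this script")
cmd <- args[1]

opts <- parse_args(OptionParser(option_list = list(
  make_option("--config", type = "character", default = NULL),
  make_option("--out", type = "character", default = "synphys_out"),
  make_option("--seed", type = "integer", default = 1L)
)), args = args[-1])

cfg <- if (is.null(opts$config)) pipeline_config() else pipeline_config(opts$config)
cfg$seed <- opts$seed

if (cmd == "make-fixtures") {
  paths <- make_fixtures(opts$out, seed = opts$seed)
  cat("wrote fixtures:\n"); cat(paste(" ", paths), sep = "\n")
} else if (cmd == "run-all") {
  run_pipeline(cfg, out_dir = opts$out)
  cat("pipeline complete in", opts$out, "\n")
} else {
  stage <- sub("-", "_", cmd, fixed = TRUE)
  run_pipeline(cfg, stages = stage, out_dir = opts$out)
  cat("stage", cmd, "complete in", opts$out, "\n")
}
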