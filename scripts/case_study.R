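#!/usr/bin/env Rscript

# Thin command-line wrapper around voidesign::run_case_study().
# Usage: Rscript scripts/case_study.R [--config <yaml>] [--mode scaled-down|full]
#                                     [--seed <int>] [--outdir <dir>]

suppressPackageStartupMessages({
  library(optparse)
  library(voidesign)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--config", type = "character", default = case_config_path()),
  make_option("--mode", type = "character", default = "scaled-down"),
  make_option("--seed", type = "integer", default = 1L),
  make_option("--outdir", type = "character", default = "case_study_out")
)))

res <- run_case_study(opts$config, mode = opts$mode, seed = opts$seed,
                      outdir = opts$outdir)
cat(readLines(file.path(res$outdir, "report.md")), sep = "\n")
cat("\noutputs in:", res$outdir, "\n")
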