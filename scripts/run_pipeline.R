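#!/usr/bin/env Rscript
# Thin command-line wrapper over halomark::run_pipeline().
# Usage: Rscript scripts/run_pipeline.R <config.txt> <out_dir>

suppressPackageStartupMessages(library(halomark))
args <- commandArgs(trailingOnly = TRUE)
if (length(args) != 2L)
  stop("usage: Rscript scripts/run_pipeline.R <config.txt> <out_dir>")
files <- run_pipeline(args[1], args[2])
cat("wrote", length(files), "outputs to", args[2], "\n")
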