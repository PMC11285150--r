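#!/usr/bin/env Rscript
# Thin command-line wrapper over the hyenamorph package.
#
# Subcommands:
#   simulate  --seed S --n N --out DIR     write a synthetic dataset
#   all       --seed S --n N --out DIR     run the full pipeline, write
#                                          every report CSV + run log
#
# Both subcommands are deterministic given --seed; all heavy lifting is
# in the package functions (see ?run_pipeline).

suppressPackageStartupMessages(library(hyenamorph))

args <- commandArgs(trailingOnly = TRUE)
usage <- function() {
  cat("usage: hyenamorph-pipeline.R {simulate|all} --seed S [--n N] --out DIR\n")
  quit(status = 2L)
}
if (length(args) < 1L) usage()
cmd <- args[[1L]]
getopt <- function(flag, default = NULL) {
  i <- match(flag, args)
  if (is.na(i) || i == length(args)) return(default)
  args[[i + 1L]]
}
seed <- getopt("--seed")
out <- getopt("--out")
if (is.null(seed) || is.null(out)) usage()
seed <- as.integer(seed)
n <- as.integer(getopt("--n", "332"))

cfg <- if (n == 332L) sim_config() else sim_config(n_specimens = n)
status <- tryCatch({
  if (cmd == "simulate") {
    ds <- simulate_hyena_dataset(cfg, seed = seed)
    write_sim_dataset(ds, out)
  } else if (cmd == "all") {
    run_pipeline(config = cfg, seed = seed, out_dir = out)
  } else usage()
  0L
}, error = function(e) {
  message("error: ", conditionMessage(e))
  1L
})
quit(status = status)
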