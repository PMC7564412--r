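#!/usr/bin/env Rscript
# Thin command-line wrapper over the tatdose package.
#
#   Rscript scripts/tatdose simulate --seed 1 --out-dir sim/
#   Rscript scripts/tatdose run-all  --seed 1 --out-dir results/ \
#       [--config cfg.yaml] [--biodist b.csv] [--survival s.csv] \
#       [--hematology h.csv]
#
# run-all with no input files analyses a synthetic study generated under the
# same seed. Exits non-zero if a required stage fails.

suppressPackageStartupMessages(library(tatdose))

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1L || !args[1L] %in% c("simulate", "run-all")) {
  stop("usage: tatdose <simulate|run-all> [--seed N] [--config FILE] ",
       "[--out-dir DIR] [--biodist CSV] [--survival CSV] [--hematology CSV]")
}
cmd <- args[1L]
opt <- function(flag, default = NULL) {
  i <- which(args == flag)
  if (length(i) == 1L && i < length(args)) args[i + 1L] else default
}

config <- read_run_config(opt("--config"))
seed <- as.integer(opt("--seed", config$seed))
out_dir <- opt("--out-dir", "tatdose_out")

if (cmd == "simulate") {
  sim <- simulate_study(config, seed = seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_biodistribution(sim$biodist, file.path(out_dir, "biodistribution.csv"))
  utils::write.csv(sim$survival, file.path(out_dir, "survival.csv"),
                   row.names = FALSE)
  utils::write.csv(sim$hematology, file.path(out_dir, "hematology.csv"),
                   row.names = FALSE)
  cat("synthetic study written to", out_dir, "\n")
  quit(status = 0L)
}

read_or_null <- function(flag, reader = utils::read.csv) {
  p <- opt(flag)
  if (is.null(p)) NULL else reader(p)
}
biodist <- read_or_null("--biodist", read_biodistribution)
survival <- read_or_null("--survival")
hematology <- read_or_null("--hematology")
if (is.null(biodist) && is.null(survival) && is.null(hematology)) {
  sim <- simulate_study(config, seed = seed)
  biodist <- sim$biodist; survival <- sim$survival
  hematology <- sim$hematology
}

res <- run_all(config, biodist = biodist, survival = survival,
               hematology = hematology, out_dir = out_dir)
if (length(res$failures)) {
  cat("stage failures:\n"); print(res$failures)
  quit(status = 1L)
}
cat("report bundle written to", out_dir, "\n")
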