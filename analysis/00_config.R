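# Shared settings for the numbered analysis drivers. Each driver is a thin
# narrative script over the rbpnet package: run them in order from the
# repository root, e.g.
#   Rscript analysis/01_simulate.R
# Outputs accumulate under results/.

suppressPackageStartupMessages(library(rbpnet))

SEED <- 20260928L
RESULTS <- "results/analysis"
RAW <- file.path(RESULTS, "raw")
dir.create(RAW, showWarnings = FALSE, recursive = TRUE)

scfg <- sim_config(seed = SEED)

write_tsv <- function(x, f) utils::write.table(
  x, file.path(RESULTS, f), sep = "\t", quote = FALSE, row.names = FALSE)

read_tsv <- function(f, ...) utils::read.delim(file.path(RESULTS, f), ...)
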