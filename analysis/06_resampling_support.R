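# Resampling test: is the called network supported by the reference
# (here the planted truth, standing in for literature PPI lists) more than
# degree-matched random networks? Stratified by interaction type.

source("analysis/00_config.R")

typed <- read_tsv("typed_edges.tsv")
truth_edges <- read_tsv("raw/truth_edges.tsv")
reference <- data.frame(a = truth_edges$bait, b = truth_edges$prey)
universe <- unique(c(truth_edges$bait, truth_edges$prey,
                     typed$bait, typed$prey))

results <- list()
for (type in unique(typed$type)) {
  sub <- typed[typed$type == type, c("bait", "prey")]
  results[[type]] <- resample_null(sub, reference, universe,
                                   mode = "bait_degree_preserving",
                                   n = 1000L, seed = SEED + 20L)
}
results$all <- resample_null(typed[, c("bait", "prey")], reference,
                             universe, mode = "bait_degree_preserving",
                             n = 1000L, seed = SEED + 21L)
sm <- resampling_summary(results)
write_tsv(sm, "resampling_summary.tsv")
print(sm, digits = 3)
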