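# Call high-confidence interacting proteins per bait and RNase condition,
# classify each interaction's RNA dependency and score the recovery
# against the planted truth.

source("analysis/00_config.R")

vals <- as.matrix(read_tsv("normalized.tsv", row.names = 1,
                           check.names = FALSE))
samples <- read_tsv("raw/ip_samples.tsv")
norm <- intensity_table(pmax(vals, 0), samples)   # container; then restore
norm$values <- vals
norm$stages <- c("log2_ppm", "batch", "zscore")
class(norm) <- c("normalized_table", class(norm))

res <- hcip_pipeline(norm)
calls <- rbind(res$calls$rnase_minus, res$calls$rnase_plus)
write_tsv(calls, "hcip_calls.tsv")
write_tsv(res$edges, "typed_edges.tsv")

truth_edges <- read_tsv("raw/truth_edges.tsv")
tk <- pair_key(truth_edges$bait, truth_edges$prey)
ck <- pair_key(res$edges$bait, res$edges$prey)
cat(sprintf("called %d interactions (%d true)\n", nrow(res$edges),
            nrow(truth_edges)))
cat(sprintf("precision %.3f, recall %.3f\n", mean(ck %in% tk),
            mean(tk %in% ck)))
for (type in c("direct", "mediated", "shielded", "undetermined")) {
  tke <- tk[truth_edges$type == type]
  cke <- ck[res$edges$type == type]
  cat(sprintf("  %-12s recall %.3f (n = %d)\n", type, mean(tke %in% cke),
              length(tke)))
}
print(table(res$edges$type))
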