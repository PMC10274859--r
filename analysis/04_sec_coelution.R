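# Average the SEC replicates, score co-elution of candidate pairs (the IP
# network plus planted complex pairs) and control the FDR against decoys.

source("analysis/00_config.R")

reps <- lapply(1:3, function(r)
  as.matrix(read_tsv(sprintf("raw/sec_rep%d.tsv", r), row.names = 1,
                     check.names = FALSE)))
elution <- average_sec_replicates(reps)

# candidate pairs: the IP network plus binary pairs from the reference
# complex catalogue (the stand-in for a CORUM-style resource)
typed <- read_tsv("typed_edges.tsv")
cx <- read_tsv("raw/complexes.tsv")
cx_pairs <- do.call(rbind, lapply(split(cx$member, cx$complex), function(m)
  if (length(m) >= 2) as.data.frame(t(utils::combn(m, 2)))))
names(cx_pairs) <- c("a", "b")
candidates <- unique(rbind(data.frame(a = typed$bait, b = typed$prey),
                           cx_pairs))

coel <- decoy_qvalues(candidates, elution, n_decoys = 1000L,
                      seed = SEED + 10L)
write_tsv(coel, "coelution.tsv")
cat(sprintf("scored %d candidate pairs; %d called at q < 0.1 (%.1f%%)\n",
            nrow(coel), sum(coel$called), 100 * mean(coel$called)))
cat(sprintf("median score of called pairs: %.3f\n",
            stats::median(coel$score[coel$called], na.rm = TRUE)))
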