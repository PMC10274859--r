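# Normalize the raw TMT reporter intensities through the fixed chain
# (MS1 apportioning -> ppm/log2 -> within-mix batch correction -> per-sample
# z-scores) and flag failed IPs.

source("analysis/00_config.R")

vals <- as.matrix(read_tsv("raw/ip_intensities.tsv", row.names = 1,
                           check.names = FALSE))
samples <- read_tsv("raw/ip_samples.tsv")
top3 <- as.matrix(read_tsv("raw/ip_top3.tsv", row.names = 1,
                           check.names = FALSE))
raw <- intensity_table(vals, samples, top3 = top3)

norm <- normalize_tmt(raw)
qc <- flag_failed_ips(norm)

utils::write.table(data.frame(protein = rownames(norm$values), norm$values,
                              check.names = FALSE),
                   file.path(RESULTS, "normalized.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
write_tsv(qc$status, "failed_ip_report.tsv")

cat("stages applied:", paste(norm$stages, collapse = " -> "), "\n")
failed <- qc$status[!qc$status$pass, ]
cat(sprintf("failed IP sets: %d (%s)\n", nrow(failed),
            paste(failed$bait, failed$condition, sep = "/", collapse = ", ")))
cat(sprintf("retained baits: %d of %d\n", length(qc$retained_baits),
            length(unique(qc$status$bait))))
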