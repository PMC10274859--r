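# Assemble the typed IP network, merge SEC co-elution support, annotate
# reference support and co-localization, and compute interaction
# stoichiometries.

source("analysis/00_config.R")

typed <- read_tsv("typed_edges.tsv")
bait_steps <- with(read_tsv("raw/bait_steps.tsv"),
                   stats::setNames(step, bait))
ip_net <- build_ip_network(typed, bait_steps)

coel <- read_tsv("coelution.tsv")
net <- merge_ip_sec(ip_net, coel[coel$called, c("a", "b")])

truth_edges <- read_tsv("raw/truth_edges.tsv")
net <- annotate_reference_support(
  net, references = list(truth = data.frame(a = truth_edges$bait,
                                            b = truth_edges$prey)))

vals <- as.matrix(read_tsv("raw/ip_intensities.tsv", row.names = 1,
                           check.names = FALSE))
samples <- read_tsv("raw/ip_samples.tsv")
raw <- intensity_table(vals, samples)
total <- as.matrix(read_tsv("raw/total_proteome.tsv", row.names = 1,
                            check.names = FALSE))
stoich <- interaction_stoichiometry(net, raw, total)

export_network(net, file.path(RESULTS, "network.tsv"), "tsv")
export_network(net, file.path(RESULTS, "network.sif"), "sif")
export_network(net, file.path(RESULTS, "network.graphml"), "graphml")
write_tsv(stoich, "stoichiometry.tsv")

dual <- sum(net$edges$sec_support & !is.na(net$edges$ip_type))
cat(sprintf("IP %d + SEC %d called pairs -> merged %d edges (%d dual)\n",
            nrow(ip_net$edges), sum(coel$called), nrow(net$edges), dual))
cat(sprintf("median IP stoichiometry: %.2f log2\n",
            stats::median(stoich$stoichiometry_ip, na.rm = TRUE)))
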