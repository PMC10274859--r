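# RNA-target co-occurrence: Jaccard indices on binding-site sets of
# interacting RBP pairs versus random pairs, and clustering of the
# all-pairs Jaccard matrix.

source("analysis/00_config.R")

site_tab <- read_tsv("raw/binding_sites.tsv")
sets <- lapply(split(site_tab$window, site_tab$rbp),
               function(w) binding_site_set("x", w))
for (nm in names(sets)) sets[[nm]]$rbp <- nm

typed <- read_tsv("typed_edges.tsv")
bait_steps <- with(read_tsv("raw/bait_steps.tsv"),
                   stats::setNames(step, bait))
net <- build_ip_network(typed, bait_steps)

cmp <- typewise_jaccard_comparison(net, sets, n_random = 500L,
                                   seed = SEED + 30L)
write_tsv(cmp$tests, "jaccard_type_tests.tsv")
print(cmp$tests, digits = 3)

# cluster the Jaccard matrix of the baits plus their called direct preys
keep <- unique(c(typed$bait, typed$prey[typed$type == "direct"]))
keep <- intersect(keep, names(sets))[seq_len(min(60, length(keep)))]
J <- jaccard_matrix(sets[keep])
cl <- cluster_jaccard_matrix(J, k = 6L)
write_tsv(data.frame(rbp = names(cl$cluster), cluster = unname(cl$cluster)),
          "jaccard_clusters.tsv")
cat(sprintf("clustered %d RBPs into %d groups\n", length(cl$cluster),
            length(unique(cl$cluster))))
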