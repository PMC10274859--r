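# Life-cycle bridge scores: which nodes sit on shortest paths between
# baits of different mRNA life-cycle steps? Reports the balanced score
# ranking and the top-3% multi-step connectors.

source("analysis/00_config.R")

net <- read_network_tsv(file.path(RESULTS, "network.tsv"))
bait_steps <- with(read_tsv("raw/bait_steps.tsv"),
                   stats::setNames(step, bait))
lc <- bait_steps[bait_steps != "control"]

bs <- bridge_score_all_steps(net, lc)
ranking <- data.frame(node = names(bs$balanced),
                      balanced = bs$balanced,
                      all_steps = bs$all_steps)
ranking <- ranking[order(-ranking$balanced), ]
write_tsv(ranking, "bridge_scores.tsv")

top_n <- max(1L, ceiling(0.03 * nrow(ranking)))
cat(sprintf("top 3%% bridge nodes (%d of %d):\n", top_n, nrow(ranking)))
print(utils::head(ranking, top_n), row.names = FALSE, digits = 3)

truth_edges <- read_tsv("raw/truth_edges.tsv")
planted <- unique(truth_edges$prey[truth_edges$planted == "bridge"])
cat(sprintf("planted connector %s ranks #%d\n", planted,
            which(ranking$node == planted)))
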