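# Prey-centric view: life-cycle step profiles per prey, hierarchical
# assignment of preys to steps, and the prey-prey Pearson correlation map.

source("analysis/00_config.R")

typed <- read_tsv("typed_edges.tsv")
bait_steps <- with(read_tsv("raw/bait_steps.tsv"),
                   stats::setNames(step, bait))
net <- build_ip_network(typed, bait_steps)

pr <- prey_step_profiles(net, bait_steps)
cl <- assign_prey_steps(pr$profiles, k = ncol(pr$profiles))
write_tsv(cbind(data.frame(prey = rownames(pr$profiles)),
                as.data.frame(pr$profiles),
                cluster = unname(cl$cluster[rownames(pr$profiles)]),
                assigned_step = unname(cl$prey_step[rownames(pr$profiles)])),
          "prey_profiles.tsv")

inc <- prey_incidence(net)
pc <- prey_correlation_matrix(inc)
utils::write.table(data.frame(prey = rownames(pc$r), pc$r,
                              check.names = FALSE),
                   file.path(RESULTS, "prey_correlation.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("%d preys profiled over %d steps\n", nrow(pr$profiles),
            ncol(pr$profiles)))
cat(sprintf("multi-step preys: %.1f%%\n", 100 * mean(pr$info$multi_step)))
print(table(cl$prey_step))
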