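# Generate the synthetic study: a ground-truth RBP interactome across 8
# mRNA life-cycle steps, raw TMT11 IP-MS reporter intensities with and
# without RNase, three SEC-MS replicate elution matrices, a total-proteome
# table and per-protein binding-site sets.

source("analysis/00_config.R")

truth <- make_truth(scfg)
print(truth)

raw <- simulate_ip(truth, scfg)
sec <- simulate_sec(truth, scfg)
total <- simulate_total_proteome(truth, scfg)
sites <- simulate_binding_sites(truth, scfg)

write_tsv(truth$edges, "raw/truth_edges.tsv")
write_tsv(data.frame(bait = names(truth$bait_steps),
                     step = unname(truth$bait_steps)),
          "raw/bait_steps.tsv")
utils::write.table(data.frame(protein = rownames(raw$values),
                              raw$values, check.names = FALSE),
                   file.path(RAW, "ip_intensities.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
write_tsv(raw$samples, "raw/ip_samples.tsv")
utils::write.table(data.frame(protein = rownames(raw$top3), raw$top3,
                              check.names = FALSE),
                   file.path(RAW, "ip_top3.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
for (r in seq_along(sec))
  utils::write.table(data.frame(protein = rownames(sec[[r]]), sec[[r]],
                                check.names = FALSE),
                     file.path(RAW, sprintf("sec_rep%d.tsv", r)),
                     sep = "\t", quote = FALSE, row.names = FALSE)
write_tsv(attr(sec, "calibration"), "raw/sec_calibration.tsv")
utils::write.table(data.frame(protein = rownames(total), total,
                              check.names = FALSE),
                   file.path(RAW, "total_proteome.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cx_tab <- do.call(rbind, lapply(seq_along(truth$complexes), function(i)
  data.frame(complex = i, member = truth$complexes[[i]],
             mass_kda = truth$complex_mass[i])))
write_tsv(cx_tab, "raw/complexes.tsv")
site_tab <- do.call(rbind, lapply(sites, function(s)
  if (length(s$sites)) data.frame(rbp = s$rbp, window = s$sites)))
write_tsv(site_tab, "raw/binding_sites.tsv")
write_tsv(attr(sites, "windows"), "raw/site_windows.tsv")

cat(sprintf("simulated %d proteins, %d true edges, %d complexes, %d mixes\n",
            length(truth$proteins), nrow(truth$edges),
            length(truth$complexes), length(unique(raw$samples$mix))))
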