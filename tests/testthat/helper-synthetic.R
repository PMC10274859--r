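# Shared fixtures, built in code. The default-config pipeline run is
# computed once per test session and reused by several test files.

tiny_config <- function(seed = 1L, ...) {
  args <- list(n_baits = 4L, n_preys = 20L, n_steps = 3L,
               preys_per_bait = 4L, n_complexes = 1L, site_universe = 60L,
               seed = seed)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}

default_run <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(seed = 101L)
      truth <- make_truth(cfg)
      raw <- simulate_ip(truth, cfg)
      norm <- normalize_tmt(raw)
      hcip <- hcip_pipeline(norm)
      cache <<- list(cfg = cfg, truth = truth, raw = raw, norm = norm,
                     hcip = hcip)
    }
    cache
  }
})

# a small hand-made normalized table: 2 mixes x (spike + 2x2 IP + 2 IgG)
toy_normalized <- function(values) {
  ss <- do.call(rbind, lapply(1:2, function(m) data.frame(
    sample_id = sprintf("m%d_%s", m, c("126", "127N", "127C", "128N", "128C")),
    mix = m, channel = c("126", "127N", "127C", "128N", "128C"),
    bait = c(NA, "B1", "B1", NA, NA),
    condition = c(NA, "rnase_minus", "rnase_minus", "rnase_minus",
                  "rnase_minus"),
    replicate = c(NA, 2 * m - 1, 2 * m, 1, 2),
    role = c("spike_in", "bait_ip", "bait_ip", "igg", "igg"),
    stringsAsFactors = FALSE)))
  tb <- intensity_table(values, ss)
  tb$stages <- c("log2_ppm", "batch", "zscore")
  class(tb) <- c("normalized_table", class(tb))
  tb
}

random_edge_df <- function(n_nodes, n_edges, seed) {
  set.seed(seed)
  nodes <- sprintf("n%02d", seq_len(n_nodes))
  all_pairs <- t(utils::combn(nodes, 2L))
  idx <- sample(nrow(all_pairs), min(n_edges, nrow(all_pairs)))
  data.frame(a = all_pairs[idx, 1], b = all_pairs[idx, 2],
             stringsAsFactors = FALSE)
}
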