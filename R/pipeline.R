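#' Pipeline run configuration
#'
#' Assembles and validates the configuration of an end-to-end run:
#' thresholds of every stage, resampling size, and the synthetic-data
#' parameters (any field of [sim_config()] may be overridden through
#' \code{sim}).
#'
#' @param seed Master seed of the run.
#' @param outdir Output directory (NULL: nothing is written).
#' @param alpha HCIP significance level.
#' @param z_threshold Enrichment z cutoff.
#' @param q_cutoff Co-elution q-value cutoff.
#' @param n_decoys Co-elution decoy count.
#' @param n_resamples Resampling-test repetitions.
#' @param sim Named list of [sim_config()] overrides.
#' @return A validated \code{run_config} list.
#' @export
run_config <- function(seed = 1L, outdir = NULL, alpha = 0.05,
                       z_threshold = 1.645, q_cutoff = 0.1,
                       n_decoys = 1000L, n_resamples = 1000L, sim = list()) {
  cfg <- list(seed = as.integer(seed), outdir = outdir, alpha = alpha,
              z_threshold = z_threshold, q_cutoff = q_cutoff,
              n_decoys = as.integer(n_decoys),
              n_resamples = as.integer(n_resamples), sim = sim)
  known_sim <- names(formals(sim_config))
  unknown <- setdiff(names(sim), known_sim)
  if (length(unknown))
    stop("unknown sim key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (cfg$alpha <= 0 || cfg$alpha >= 1 || cfg$q_cutoff <= 0 || cfg$q_cutoff >= 1)
    stop("alpha and q_cutoff must lie in (0, 1)", call. = FALSE)
  structure(cfg, class = "run_config")
}

#' Load a run configuration from a YAML file
#'
#' Unknown keys are rejected by name; missing keys take their defaults.
#'
#' @param path YAML file.
#' @return A \code{run_config}.
#' @export
load_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(run_config, raw)
}

#' Save a run configuration to YAML
#'
#' @param config A \code{run_config}.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
save_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the full synthetic-data pipeline end to end
#'
#' Simulate -> normalize -> HCIP calling -> RNA-dependency classification
#' -> SEC co-elution -> network merge and annotation -> stoichiometry ->
#' resampling support test -> bridge scores -> prey profiles -> Jaccard
#' co-occurrence. Every stage runs from the previous stage's in-memory
#' output; when \code{config$outdir} is set, each stage's table is also
#' written as TSV. Deterministic for a fixed seed.
#'
#' @param config A [run_config()].
#' @return A run report: list with the truth, the per-stage outputs and a
#'   \code{counts} summary.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  scfg <- do.call(sim_config, c(list(seed = config$seed), config$sim))
  truth <- make_truth(scfg)

  raw <- simulate_ip(truth, scfg)
  norm <- normalize_tmt(raw)
  hcip <- hcip_pipeline(norm, alpha = config$alpha,
                        z_threshold = config$z_threshold)
  ip_net <- build_ip_network(hcip$edges, truth$bait_steps)

  sec_reps <- simulate_sec(truth, scfg)
  elution <- average_sec_replicates(sec_reps)
  complex_pairs <- do.call(rbind, lapply(truth$complexes, function(cx)
    t(utils::combn(cx, 2L))))
  candidates <- unique(rbind(as.matrix(ip_net$edges[, c("a", "b")]),
                             complex_pairs))
  coel <- decoy_qvalues(candidates, elution, n_decoys = config$n_decoys,
                        seed = config$seed + 10L,
                        q_cutoff = config$q_cutoff)
  net <- merge_ip_sec(ip_net, coel[coel$called, c("a", "b")])

  truth_pairs <- data.frame(a = truth$edges$bait, b = truth$edges$prey)
  net <- annotate_reference_support(net, references = list(truth = truth_pairs))

  total <- simulate_total_proteome(truth, scfg)
  stoich <- interaction_stoichiometry(net, raw, total)

  resamp <- resample_null(hcip$edges[, c("bait", "prey")], truth_pairs,
                          universe = truth$proteins,
                          mode = "bait_degree_preserving",
                          n = config$n_resamples, seed = config$seed + 20L)

  lc_steps <- truth$bait_steps[truth$bait_steps != "control"]
  bridge <- bridge_score_all_steps(net, lc_steps)

  profiles <- prey_step_profiles(ip_net, truth$bait_steps)
  inc <- prey_incidence(ip_net)
  prey_cor <- prey_correlation_matrix(inc)

  sites <- simulate_binding_sites(truth, scfg)
  jac <- typewise_jaccard_comparison(ip_net, sites,
                                     seed = config$seed + 30L)

  counts <- c(proteins = length(truth$proteins),
              true_edges = nrow(truth$edges),
              ip_edges = nrow(ip_net$edges),
              sec_called = sum(coel$called),
              merged_edges = nrow(net$edges),
              dual_support = sum(net$edges$sec_support &
                                   !is.na(net$edges$ip_type)))
  report <- list(seed = config$seed, config = config, truth = truth,
                 norm = norm, hcip = hcip, ip_network = ip_net,
                 coelution = coel, network = net, stoichiometry = stoich,
                 resampling = resamp, bridge = bridge,
                 prey_profiles = profiles, prey_correlation = prey_cor,
                 jaccard = jac, counts = counts)

  if (!is.null(config$outdir)) {
    dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
    wt <- function(x, f) utils::write.table(
      x, file.path(config$outdir, f), sep = "\t", quote = FALSE,
      row.names = FALSE)
    wt(truth$edges, "truth_edges.tsv")
    wt(hcip$edges, "hcip_edges.tsv")
    wt(coel, "coelution.tsv")
    export_network(net, file.path(config$outdir, "network.tsv"), "tsv")
    wt(stoich, "stoichiometry.tsv")
    wt(data.frame(node = names(bridge$balanced),
                  balanced = bridge$balanced,
                  all_steps = bridge$all_steps)[
                    order(-bridge$balanced), ], "bridge_scores.tsv")
    wt(jac$tests, "jaccard_tests.tsv")
    wt(data.frame(stat = names(counts), value = as.integer(counts)),
       "run_report.tsv")
  }
  report
}
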