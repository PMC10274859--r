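#' Simulate a total-proteome abundance table
#'
#' Strictly positive log-normal abundances per protein with independent
#' replicate noise. Members of a planted complex share one baseline
#' abundance (co-regulated 1:1 subunits), so their pairwise abundance
#' log-ratios are centred at zero, as expected for stable complexes.
#'
#' @param truth A [make_truth()] result.
#' @param config The matching [sim_config()].
#' @param n_replicates Number of replicate measurements (default 3).
#' @param equal_complex_abundance Give complex members a shared baseline.
#' @return Numeric matrix, proteins x replicates, raw intensities.
#' @export
simulate_total_proteome <- function(truth, config, n_replicates = 3L,
                                    equal_complex_abundance = TRUE) {
  stopifnot(inherits(truth, "synthetic_truth"), inherits(config, "sim_config"))
  set.seed(config$seed + 3L)
  proteins <- truth$proteins
  base <- stats::rnorm(length(proteins), config$background_mu,
                       config$background_sigma)
  names(base) <- proteins
  if (equal_complex_abundance)
    for (cx in truth$complexes)
      base[cx] <- base[cx[1]]
  noise <- matrix(stats::rnorm(length(proteins) * n_replicates, 0,
                               config$noise_sigma),
                  length(proteins), n_replicates)
  out <- 2^(base + noise)
  dimnames(out) <- list(proteins, paste0("rep", seq_len(n_replicates)))
  out
}
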