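#' Configuration for the synthetic interactome generator
#'
#' Bundles every knob of the synthetic-data generator: the study design
#' (baits, preys, TMT11 mix layout), the intensity model (log-normal
#' background, planted enrichment effect, missingness), the SEC elution
#' model and the binding-site overlap model. The defaults emulate the
#' design of an RNase +/- IP-MS screen: each TMT11 mix carries one pooled
#' spike-in (channel 126), three RNase-treated IPs, three untreated IPs and
#' 2 + 2 IgG controls, with bait replicates rotated across mixes so that no
#' mix contains two replicates of the same bait.
#'
#' @param n_baits Number of bait proteins. One bait is reserved as a
#'   negative control (an MCM2-like protein with a private complex,
#'   disconnected from the life-cycle network) and one life-cycle bait is
#'   planted to fail IP quality control in one RNase condition so that its
#'   preys become "undetermined".
#' @param n_preys Number of prey proteins in the pool.
#' @param n_steps Number of mRNA life-cycle steps spanned by the baits
#'   (transcription, splicing, ..., degradation).
#' @param preys_per_bait Expected number of true interactors per
#'   life-cycle bait.
#' @param type_proportions Named numeric vector of interaction-type
#'   frequencies over \code{direct}, \code{mediated}, \code{shielded},
#'   \code{undetermined}; must sum to 1.
#' @param n_complexes Number of co-eluting complexes planted in the SEC
#'   simulation (in addition to the control bait's private complex).
#' @param background_mu,background_sigma Mean and sd of the between-protein
#'   log2 baseline intensity (log-normal background).
#' @param noise_sigma Channel-to-channel log2 measurement noise sd. Also
#'   used for the spike-in channel so that \code{noise_sigma = 0} makes the
#'   spike-in exactly the mean of the other channels.
#' @param effect_size Planted log2 enrichment of a true interactor (and of
#'   the bait itself) in the bait's IP channels.
#' @param bridge_effect_drop Reduction (log2) of the enrichment of the
#'   planted bridge prey's interactions: multi-step connectors bind their
#'   many partners substoichiometrically, so their IP enrichment is weaker
#'   than that of stable complex members.
#' @param dropout_threshold Raw intensity below which a value is recorded
#'   as missing (intensity-dependent, missing-not-at-random dropout).
#' @param n_fractions Number of SEC fractions; fractions are labelled
#'   \code{first_fraction} .. \code{first_fraction + n_fractions - 1}
#'   (default 10..66, the protein-containing fractions).
#' @param first_fraction Label of the first SEC fraction.
#' @param sec_noise Multiplicative log2 noise sd of an SEC replicate.
#' @param complex_fraction_of_mass Fraction of a complex member's signal
#'   placed under the complex apex (the remainder elutes as monomer).
#' @param site_universe Number of binding-site windows in the synthetic
#'   transcriptome.
#' @param baseline_site_rate Per-window inclusion probability of a site in
#'   a protein's binding-site set, absent any interaction coupling.
#' @param overlap_rho Named numeric vector in \[0, 1\]: per interaction
#'   type, the probability that an interacting partner inherits a window's
#'   occupancy state from the other partner (site-sharing strength).
#' @param seed Integer seed; every generator is a pure function of
#'   (truth, config, seed).
#'
#' @return An object of class \code{sim_config} (a validated list).
#' @export
sim_config <- function(n_baits = 12L,
                       n_preys = 300L,
                       n_steps = 8L,
                       preys_per_bait = 30L,
                       type_proportions = c(direct = 0.20, mediated = 0.26,
                                            shielded = 0.47, undetermined = 0.07),
                       n_complexes = 10L,
                       background_mu = 20,
                       background_sigma = 1.5,
                       noise_sigma = 0.3,
                       effect_size = 3.0,
                       bridge_effect_drop = 1.0,
                       dropout_threshold = 2^15.5,
                       n_fractions = 57L,
                       first_fraction = 10L,
                       sec_noise = 0.3,
                       complex_fraction_of_mass = 0.7,
                       site_universe = 500L,
                       baseline_site_rate = 0.10,
                       overlap_rho = c(direct = 0.55, mediated = 0.25,
                                       shielded = 0.35, undetermined = 0.60),
                       seed = 1L) {
  cfg <- list(n_baits = as.integer(n_baits), n_preys = as.integer(n_preys),
              n_steps = as.integer(n_steps),
              preys_per_bait = as.integer(preys_per_bait),
              type_proportions = type_proportions,
              n_complexes = as.integer(n_complexes),
              background_mu = background_mu, background_sigma = background_sigma,
              noise_sigma = noise_sigma, effect_size = effect_size,
              bridge_effect_drop = bridge_effect_drop,
              dropout_threshold = dropout_threshold,
              n_fractions = as.integer(n_fractions),
              first_fraction = as.integer(first_fraction),
              sec_noise = sec_noise,
              complex_fraction_of_mass = complex_fraction_of_mass,
              site_universe = as.integer(site_universe),
              baseline_site_rate = baseline_site_rate,
              overlap_rho = overlap_rho,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  types <- c("direct", "mediated", "shielded", "undetermined")
  counts <- c("n_baits", "n_preys", "n_steps", "preys_per_bait",
              "n_fractions", "site_universe")
  for (nm in counts) {
    if (length(cfg[[nm]]) != 1L || is.na(cfg[[nm]]) || cfg[[nm]] <= 0L)
      stop(sprintf("configuration error: '%s' must be a positive count", nm),
           call. = FALSE)
  }
  if (cfg$n_complexes < 0L)
    stop("configuration error: 'n_complexes' must be >= 0", call. = FALSE)
  tp <- cfg$type_proportions
  if (!setequal(names(tp), types))
    stop("configuration error: 'type_proportions' must be named over ",
         paste(types, collapse = ", "), call. = FALSE)
  if (any(tp < 0) || abs(sum(tp) - 1) > 1e-9)
    stop("configuration error: 'type_proportions' must be non-negative and sum to 1",
         call. = FALSE)
  rho <- cfg$overlap_rho
  if (!setequal(names(rho), types) || any(rho < 0) || any(rho > 1))
    stop("configuration error: 'overlap_rho' must be named over the four ",
         "interaction types with values in [0, 1]", call. = FALSE)
  if (cfg$background_sigma < 0 || cfg$noise_sigma < 0 || cfg$sec_noise < 0)
    stop("configuration error: noise parameters must be non-negative",
         call. = FALSE)
  if (cfg$n_baits < 4L)
    stop("configuration error: need at least 4 baits (control + failing bait + 2)",
         call. = FALSE)
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic interactome configuration\n")
  cat(sprintf("  baits: %d (%d life-cycle steps, 1 negative control)\n",
              x$n_baits, x$n_steps))
  cat(sprintf("  preys: %d; expected preys/bait: %d\n",
              x$n_preys, x$preys_per_bait))
  cat(sprintf("  type proportions: %s\n",
              paste(sprintf("%s %.2f", names(x$type_proportions),
                            x$type_proportions), collapse = ", ")))
  cat(sprintf("  effect size: %.1f log2; background N(%.1f, %.1f); noise sd %.2f\n",
              x$effect_size, x$background_mu, x$background_sigma, x$noise_sigma))
  cat(sprintf("  SEC: %d fractions (%d..%d), %d planted complexes\n",
              x$n_fractions, x$first_fraction,
              x$first_fraction + x$n_fractions - 1L, x$n_complexes))
  invisible(x)
}
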