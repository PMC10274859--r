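#' SEC fraction -> apparent mass calibration
#'
#' Log-linear calibration over the protein-containing fractions: apparent
#' mass decreases exponentially with fraction index, spanning ~5 MDa at
#' the first fraction down to ~10 kDa at the last.
#'
#' @param fractions Integer vector of fraction labels.
#' @param mass_range Apparent mass (kDa) at the first and last fraction.
#' @return Data frame with columns \code{fraction}, \code{mass_kda}.
#' @export
sec_calibration <- function(fractions, mass_range = c(5000, 10)) {
  stopifnot(length(fractions) >= 2L, all(diff(fractions) > 0))
  lm_ <- log10(mass_range)
  slope <- (lm_[2] - lm_[1]) / (fractions[length(fractions)] - fractions[1])
  data.frame(fraction = fractions,
             mass_kda = 10^(lm_[1] + slope * (fractions - fractions[1])))
}

#' Map a mass to its expected apex fraction
#'
#' Inverse of [sec_calibration()] by log-linear interpolation; masses
#' outside the calibrated range are clamped with a warning.
#'
#' @param mass_kda Numeric vector of apparent masses (kDa).
#' @param calibration A [sec_calibration()] data frame.
#' @return Numeric vector of (fractional) apex positions.
#' @export
mass_to_fraction <- function(mass_kda, calibration) {
  rng <- range(calibration$mass_kda)
  if (any(mass_kda < rng[1] | mass_kda > rng[2])) {
    warning("mass outside calibration range, clamped", call. = FALSE)
    mass_kda <- pmin(pmax(mass_kda, rng[1]), rng[2])
  }
  stats::approx(log10(calibration$mass_kda), calibration$fraction,
                xout = log10(mass_kda), rule = 2)$y
}

#' Simulate SEC elution profiles
#'
#' Every protein elutes as a Gaussian monomer peak at the fraction implied
#' by its monomer mass; members of a planted complex additionally share a
#' Gaussian apex at the fraction implied by the complex mass, carrying
#' \code{complex_fraction_of_mass} of their signal. Replicates receive
#' independent multiplicative log2 noise; intensities below the dropout
#' threshold (scaled to the SEC intensity range) are missing.
#'
#' @param truth A [make_truth()] result.
#' @param config The matching [sim_config()].
#' @param n_replicates Number of replicate runs (default 3).
#' @return List of \code{n_replicates} elution matrices (protein x
#'   fraction, fraction labels as column names) with the calibration
#'   attached as \code{attr(, "calibration")}.
#' @export
simulate_sec <- function(truth, config, n_replicates = 3L) {
  stopifnot(inherits(truth, "synthetic_truth"), inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  fractions <- seq(config$first_fraction,
                   length.out = config$n_fractions)
  calib <- sec_calibration(fractions)
  proteins <- truth$proteins
  P <- length(proteins)

  abundance <- 2^stats::rnorm(P, config$background_mu, config$background_sigma)
  names(abundance) <- proteins
  mono_apex <- mass_to_fraction(truth$monomer_mass[proteins], calib)
  width <- 1.5

  in_complex <- lapply(seq_along(truth$complexes), function(i) truth$complexes[[i]])
  cplx_apex <- suppressWarnings(
    mass_to_fraction(truth$complex_mass, calib))

  mono_share <- rep(1, P); names(mono_share) <- proteins
  signal <- matrix(0, P, length(fractions),
                   dimnames = list(proteins, as.character(fractions)))
  for (i in seq_along(in_complex)) {
    m <- intersect(in_complex[[i]], proteins)
    mono_share[m] <- mono_share[m] - config$complex_fraction_of_mass
    prof <- exp(-((fractions - cplx_apex[i])^2) / (2 * width^2))
    signal[m, ] <- signal[m, ] +
      config$complex_fraction_of_mass * abundance[m] %o% prof
  }
  mono_share[mono_share < 0] <- 0
  mono_prof <- exp(-(outer(mono_apex, fractions, `-`)^2) / (2 * width^2))
  signal <- signal + (mono_share * abundance) * mono_prof

  floor_ <- config$dropout_threshold / 50   # SEC runs on less material
  reps <- lapply(seq_len(n_replicates), function(r) {
    noisy <- signal * 2^matrix(stats::rnorm(length(signal), 0, config$sec_noise),
                               P, length(fractions))
    noisy[noisy < floor_] <- NA_real_
    noisy
  })
  attr(reps, "calibration") <- calib
  reps
}
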