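#' TMT11 channel labels
#' @keywords internal
tmt11_channels <- function() {
  c("126", "127N", "127C", "128N", "128C", "129N", "129C",
    "130N", "130C", "131N", "131C")
}

#' Build the TMT11 sample sheet for a truth object
#'
#' One mix per bait count; each mix carries one spike-in (channel 126),
#' three RNase-minus IPs and three RNase-plus IPs of three *distinct* baits
#' (one replicate each, replicates of a bait rotated across mixes so no two
#' replicates share a mix), and 2 + 2 IgG controls. This reproduces the
#' multiplexing layout of an RNase +/- IP screen where replicates of the
#' same bait never co-occur in a mix.
#'
#' @param truth A [make_truth()] result.
#' @param n_replicates Replicates per bait and condition (default 3).
#' @return Data frame sample sheet (see [intensity_table()]).
#' @export
ip_sample_sheet <- function(truth, n_replicates = 3L) {
  baits <- truth$baits
  n_mixes <- length(baits)
  # shift such that the n_replicates rotated copies of the bait list place
  # distinct baits in each mix
  shift <- NA_integer_
  for (s in seq_len(n_mixes - 1L)) {
    if (all((s * seq_len(n_replicates - 1L)) %% n_mixes != 0L)) {
      shift <- s; break
    }
  }
  if (is.na(shift))
    stop("cannot build a replicate rotation for ", n_mixes, " mixes",
         call. = FALSE)
  ch <- tmt11_channels()
  minus_ch <- ch[2:4]; plus_ch <- ch[5:7]
  igg_minus <- ch[8:9]; igg_plus <- ch[10:11]

  rows <- list()
  add <- function(mix, channel, bait, condition, replicate, role) {
    rows[[length(rows) + 1L]] <<- data.frame(
      sample_id = sprintf("mix%02d_%s", mix, channel),
      mix = mix, channel = channel, bait = bait, condition = condition,
      replicate = replicate, role = role, stringsAsFactors = FALSE)
  }
  for (m in seq_len(n_mixes)) {
    add(m, ch[1], NA_character_, NA_character_, NA_integer_, "spike_in")
    for (r in seq_len(n_replicates)) {
      b_idx <- ((m - 1L) - shift * (r - 1L)) %% n_mixes + 1L
      add(m, minus_ch[r], baits[b_idx], "rnase_minus", r, "bait_ip")
      add(m, plus_ch[r], baits[b_idx], "rnase_plus", r, "bait_ip")
    }
    for (k in 1:2) {
      add(m, igg_minus[k], NA_character_, "rnase_minus", k, "igg")
      add(m, igg_plus[k], NA_character_, "rnase_plus", k, "igg")
    }
  }
  do.call(rbind, rows)
}

#' Simulate a TMT11 IP-MS reporter-intensity table
#'
#' Generates raw reporter intensities for every mix of the design in
#' [ip_sample_sheet()]. Background log2 intensities are log-normal
#' (protein baseline ~ N(background_mu, background_sigma), channel noise
#' ~ N(0, noise_sigma)). Each bait is self-enriched by \code{effect_size}
#' log2 units in its own IP channels; true interactors are enriched
#' according to their type: direct in both conditions, RNA-mediated only
#' without RNase, RNA-shielded only with RNase. The designated failing
#' bait's IP carries no enrichment at all (bait included) in its failing
#' condition, so quality control later routes it to the background pool and
#' its preys become undetermined. IgG channels carry no planted
#' enrichment. The spike-in channel is the linear-scale mean of all other
#' channels of the mix times multiplicative noise; values below
#' \code{dropout_threshold} are set missing (intensity-dependent dropout).
#'
#' @param truth A [make_truth()] result.
#' @param config The [sim_config()] used to build it.
#' @return A raw [intensity_table()] with Top3 MS1 quantities attached.
#' @export
simulate_ip <- function(truth, config) {
  stopifnot(inherits(truth, "synthetic_truth"), inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  ss <- ip_sample_sheet(truth)
  proteins <- truth$proteins
  P <- length(proteins); S <- nrow(ss)

  base <- stats::rnorm(P, config$background_mu, config$background_sigma)
  names(base) <- proteins
  log2v <- matrix(base, nrow = P, ncol = S,
                  dimnames = list(proteins, ss$sample_id))
  log2v <- log2v + matrix(stats::rnorm(P * S, 0, config$noise_sigma), P, S)

  fail_cond <- truth$undetermined_fail_condition
  enrich_cols <- function(bait, condition) {
    which(ss$role == "bait_ip" & ss$bait == bait & ss$condition == condition)
  }
  conds <- c("rnase_minus", "rnase_plus")
  ok_conds <- function(bait) {
    if (identical(bait, truth$undetermined_bait)) setdiff(conds, fail_cond)
    else conds
  }
  # bait self-enrichment
  for (b in truth$baits)
    for (cond in ok_conds(b))
      log2v[b, enrich_cols(b, cond)] <-
        log2v[b, enrich_cols(b, cond)] + config$effect_size
  # prey enrichment by interaction type
  type_conds <- list(direct = conds, mediated = "rnase_minus",
                     shielded = "rnase_plus",
                     undetermined = setdiff(conds, fail_cond))
  for (i in seq_len(nrow(truth$edges))) {
    e <- truth$edges[i, ]
    eff <- if (identical(e$planted, "bridge"))
      config$effect_size - config$bridge_effect_drop
    else config$effect_size
    for (cond in intersect(type_conds[[e$type]], ok_conds(e$bait)))
      log2v[e$prey, enrich_cols(e$bait, cond)] <-
        log2v[e$prey, enrich_cols(e$bait, cond)] + eff
  }

  linear <- 2^log2v
  # spike-in: per-protein mean of all other channels of the mix, plus noise
  for (m in unique(ss$mix)) {
    cols <- which(ss$mix == m)
    spike <- cols[ss$role[cols] == "spike_in"]
    rest <- setdiff(cols, spike)
    linear[, spike] <- rowMeans(linear[, rest, drop = FALSE]) *
      2^stats::rnorm(P, 0, config$noise_sigma)
  }
  linear[linear < config$dropout_threshold] <- NA_real_

  mixes <- sort(unique(ss$mix))
  top3 <- matrix(2^(base + stats::rnorm(P * length(mixes), 0, 0.2)) * 3,
                 nrow = P, dimnames = list(proteins, as.character(mixes)))
  intensity_table(linear, ss, top3 = top3)
}
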