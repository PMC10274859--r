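#' Life-cycle step labels used by the generator
#'
#' @param n_steps Number of steps requested.
#' @return Character vector of step names.
#' @keywords internal
life_cycle_steps <- function(n_steps) {
  steps <- c("transcription", "splicing", "modification", "three_prime",
             "nuclear_export", "localization", "translation", "degradation")
  if (n_steps <= length(steps)) steps[seq_len(n_steps)]
  else c(steps, paste0("step_", seq_len(n_steps - length(steps)) + length(steps)))
}

#' Generate a ground-truth interactome
#'
#' Draws the hidden state that every synthetic raw-data generator conditions
#' on: bait identities and life-cycle step assignments, the set of true
#' bait--prey edges with their RNA-dependency type, co-eluting complexes
#' with monomer and complex masses, and one planted "bridge" prey that is
#' wired to one bait of every life-cycle step (a multi-step connector that
#' the bridge-score analysis should rank first).
#'
#' Interaction types are drawn i.i.d. from \code{config$type_proportions}.
#' All undetermined-type edges are routed to one designated life-cycle bait
#' whose IP is later forced to fail quality control in the RNase-treated
#' condition; this mirrors the operational definition of "undetermined"
#' (the class is a property of the bait's IP, not of the edge). The last
#' bait is a negative control carrying a private 5-member complex that is
#' disconnected from the life-cycle network.
#'
#' @param config A [sim_config()].
#' @return A \code{synthetic_truth} list with elements \code{proteins},
#'   \code{baits}, \code{bait_steps}, \code{control_bait},
#'   \code{undetermined_bait}, \code{undetermined_fail_condition},
#'   \code{edges} (data.frame: bait, prey, type, planted),
#'   \code{complexes}, \code{monomer_mass}, \code{complex_mass},
#'   \code{planted_bridge}.
#' @export
make_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  set.seed(config$seed)

  n_lc <- config$n_baits - 1L           # life-cycle baits; last bait is control
  baits <- sprintf("BAIT_%02d", seq_len(config$n_baits))
  control_bait <- baits[config$n_baits]
  lc_baits <- baits[seq_len(n_lc)]
  steps <- rep(life_cycle_steps(config$n_steps), length.out = n_lc)
  bait_steps <- c(stats::setNames(steps, lc_baits),
                  stats::setNames("control", control_bait))

  preys <- sprintf("PREY_%04d", seq_len(config$n_preys))
  if (config$n_preys < 8L)
    stop("configuration error: need at least 8 preys", call. = FALSE)
  control_preys <- utils::tail(preys, 4L)           # private control complex
  bridge <- preys[1L]
  pool <- setdiff(preys, c(control_preys, bridge))

  # undetermined edges concentrate on one bait whose +RNase IP will fail QC
  undet_bait <- lc_baits[n_lc]

  n_edges <- n_lc * config$preys_per_bait
  types <- sample(names(config$type_proportions), n_edges, replace = TRUE,
                  prob = config$type_proportions)
  n_undet <- sum(types == "undetermined")
  other_types <- types[types != "undetermined"]
  other_baits <- setdiff(lc_baits, undet_bait)

  edges <- list()
  if (n_undet > 0L)
    edges[[length(edges) + 1L]] <- data.frame(
      bait = undet_bait,
      prey = sample(pool, min(n_undet, length(pool))),
      type = "undetermined", planted = "regular",
      stringsAsFactors = FALSE)
  bait_of <- sample(other_baits, length(other_types), replace = TRUE)
  for (b in other_baits) {
    tb <- other_types[bait_of == b]
    if (!length(tb)) next
    edges[[length(edges) + 1L]] <- data.frame(
      bait = b, prey = sample(pool, min(length(tb), length(pool))),
      type = tb[seq_len(min(length(tb), length(pool)))],
      planted = "regular", stringsAsFactors = FALSE)
  }

  # planted bridge: one bait per distinct step, detected in both conditions
  step_reps <- lc_baits[!duplicated(steps)]
  step_reps <- setdiff(step_reps, undet_bait)
  edges[[length(edges) + 1L]] <- data.frame(
    bait = step_reps, prey = bridge, type = "direct", planted = "bridge",
    stringsAsFactors = FALSE)

  # negative-control bait: private complex, direct edges only
  edges[[length(edges) + 1L]] <- data.frame(
    bait = control_bait, prey = control_preys, type = "direct",
    planted = "control", stringsAsFactors = FALSE)

  edges <- do.call(rbind, edges)
  rownames(edges) <- NULL

  proteins <- c(baits, preys)
  monomer_mass <- stats::setNames(stats::runif(length(proteins), 20, 150),
                                  proteins)

  # complexes co-elute in SEC, which is run without RNase: a complex is a
  # bait plus some of its RNA-independent (direct) or RNA-scaffolded
  # (mediated) preys, so IP edges can earn orthogonal SEC support and
  # prey-prey pairs appear in the co-elution network
  complexes <- list(c(control_bait, control_preys))
  used <- character(0)
  cx_baits <- rep(other_baits, length.out = config$n_complexes)
  for (i in seq_len(config$n_complexes)) {
    b <- cx_baits[i]
    cand <- setdiff(edges$prey[edges$bait == b &
                                 edges$type %in% c("direct", "mediated")],
                    used)
    size <- sample(2:4, 1L)
    members <- utils::head(cand, size)
    if (length(members) < 2L)
      members <- c(members,
                   sample(setdiff(pool, c(used, members)),
                          2L - length(members)))
    used <- c(used, members)
    complexes[[length(complexes) + 1L]] <- c(b, members)
  }
  complex_mass <- vapply(complexes,
                         function(m) sum(monomer_mass[m]), numeric(1))

  structure(list(proteins = proteins, baits = baits,
                 bait_steps = bait_steps, control_bait = control_bait,
                 undetermined_bait = undet_bait,
                 undetermined_fail_condition = "rnase_plus",
                 edges = edges, complexes = complexes,
                 monomer_mass = monomer_mass, complex_mass = complex_mass,
                 planted_bridge = bridge),
            class = "synthetic_truth")
}

#' Unordered-pair keys for a set of edges
#'
#' @param a,b Character vectors of endpoints.
#' @return Character vector of canonical \code{"min|max"} keys.
#' @export
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("Synthetic truth: %d proteins, %d baits, %d true edges, %d complexes\n",
              length(x$proteins), length(x$baits), nrow(x$edges),
              length(x$complexes)))
  cat(sprintf("  planted bridge: %s; control bait: %s; failing bait: %s (%s)\n",
              x$planted_bridge, x$control_bait, x$undetermined_bait,
              x$undetermined_fail_condition))
  print(table(x$edges$type))
  invisible(x)
}
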