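#' Replicate enrichment counts for one bait IP
#'
#' For each protein, counts in how many replicate channels of the given
#' bait and RNase condition its per-sample z-score exceeds
#' \code{z_threshold} (strict inequality; 1.645 is the upper 5% tail of a
#' standard normal, i.e. "within the top 5% of measured proteins").
#' Missing values count as not enriched.
#'
#' @param norm A \code{normalized_table} (see [zscore_samples()]).
#' @param bait,condition Bait id and RNase condition.
#' @param z_threshold z cutoff (default 1.645).
#' @return Named integer vector of replicate counts per protein.
#' @export
replicate_enrichment_flags <- function(norm, bait, condition,
                                       z_threshold = 1.645) {
  stopifnot(inherits(norm, "normalized_table"))
  ss <- norm$samples
  cols <- which(ss$role == "bait_ip" & ss$bait == bait &
                  ss$condition == condition)
  if (length(cols) < 2L)
    stop("insufficient replicates for bait ", bait, " in ", condition,
         call. = FALSE)
  z <- norm$values[, cols, drop = FALSE]
  rowSums(!is.na(z) & z > z_threshold)
}

#' Pooled background values per protein
#'
#' The enrichment background for a condition is the pooled signal of all
#' IgG control channels of that RNase condition plus the channels of
#' failed IPs in that condition.
#'
#' @param norm A \code{normalized_table}.
#' @param condition RNase condition.
#' @param failed_samples Sample ids of failed IPs (from
#'   [flag_failed_ips()]).
#' @return Numeric matrix, proteins x pooled background samples.
#' @export
background_pool <- function(norm, condition, failed_samples = character(0)) {
  stopifnot(inherits(norm, "normalized_table"))
  ss <- norm$samples
  igg <- ss$sample_id[ss$role == "igg" & ss$condition == condition]
  failed <- intersect(failed_samples,
                      ss$sample_id[ss$condition %in% condition])
  cols <- union(igg, failed)
  if (!length(cols))
    stop("empty background pool for condition ", condition, call. = FALSE)
  norm$values[, cols, drop = FALSE]
}

#' One-sided rank-sum p-value (prey > background)
#'
#' Exact by enumeration of rank subsets (midranks, so ties are handled)
#' when the number of subsets is small enough; otherwise the normal
#' approximation with continuity correction via [stats::wilcox.test()].
#' Degenerate all-tied input returns p = 1.
#'
#' @param x,y Numeric vectors (x tested as stochastically greater).
#' @param max_enum Enumerate exactly when \code{choose(n, nx) <= max_enum}.
#' @return A p-value in (0, 1].
#' @keywords internal
rank_sum_p <- function(x, y, max_enum = 5e4) {
  n1 <- length(x); n <- n1 + length(y)
  all_v <- c(x, y)
  if (length(unique(all_v)) == 1L) return(1)
  r <- rank(all_v)
  W <- sum(r[seq_len(n1)])
  if (choose(n, n1) <= max_enum) {
    idx <- utils::combn(n, n1)
    Wp <- colSums(matrix(r[idx], nrow = n1))
    mean(Wp >= W - 1e-9)
  } else {
    suppressWarnings(stats::wilcox.test(x, y, alternative = "greater",
                                        exact = FALSE, correct = TRUE)$p.value)
  }
}

#' Enrichment statistics for one prey against the background
#'
#' @param prey_values Numeric vector of the prey's normalized values in the
#'   bait's replicate channels (missing dropped).
#' @param background_values Numeric vector of the prey's values in the
#'   pooled background (missing dropped).
#' @return List with \code{log2_ratio} (difference of medians on the
#'   normalized log2 scale) and \code{p_value} (one-sided rank-sum).
#' @export
test_enrichment <- function(prey_values, background_values) {
  x <- prey_values[!is.na(prey_values)]
  y <- background_values[!is.na(background_values)]
  if (length(x) < 2L || length(y) < 4L)
    return(list(log2_ratio = NA_real_, p_value = NA_real_))
  list(log2_ratio = stats::median(x) - stats::median(y),
       p_value = rank_sum_p(x, y))
}

#' Call high-confidence interacting proteins for one bait and condition
#'
#' A prey passes when (i) it is enriched (z > \code{z_threshold}) in at
#' least \code{min_reps} replicates of the bait's IP, (ii) its log2 ratio
#' of median IP signal over median pooled background exceeds
#' \code{min_ratio}, and (iii) the one-sided rank-sum p against the
#' background is below \code{alpha}. The bait's own row is excluded.
#'
#' @param norm A \code{normalized_table}.
#' @param bait,condition Bait id and RNase condition (the bait must have
#'   passed IP quality control in this condition).
#' @param background Matrix from [background_pool()].
#' @param alpha Significance level (0.05 default; 0.01 available as a
#'   per-bait override for high-signal baits).
#' @param z_threshold,min_reps,min_ratio Thresholds of criteria (i)-(ii).
#' @return Data frame of HCIP calls (one row per eligible prey) with
#'   columns bait, prey, condition, n_enriched_reps, log2_ratio, p_value,
#'   alpha_used, pass.
#' @export
call_hcips <- function(norm, bait, condition, background,
                       alpha = 0.05, z_threshold = 1.645,
                       min_reps = 2L, min_ratio = 1) {
  counts <- replicate_enrichment_flags(norm, bait, condition, z_threshold)
  ss <- norm$samples
  cols <- which(ss$role == "bait_ip" & ss$bait == bait &
                  ss$condition == condition)
  eligible <- setdiff(names(counts)[counts >= min_reps], bait)
  out <- data.frame(bait = character(0), prey = character(0),
                    condition = character(0), n_enriched_reps = integer(0),
                    log2_ratio = numeric(0), p_value = numeric(0),
                    alpha_used = numeric(0), pass = logical(0),
                    stringsAsFactors = FALSE)
  for (p in eligible) {
    st <- test_enrichment(norm$values[p, cols], background[p, ])
    pass <- !is.na(st$log2_ratio) && !is.na(st$p_value) &&
      st$log2_ratio > min_ratio && st$p_value < alpha
    out <- rbind(out, data.frame(
      bait = bait, prey = p, condition = condition,
      n_enriched_reps = counts[[p]], log2_ratio = st$log2_ratio,
      p_value = st$p_value, alpha_used = alpha, pass = pass,
      stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' Classify the RNA dependency of each bait-prey interaction
#'
#' An interaction called in both RNase conditions is \code{direct}; called
#' only without RNase, \code{mediated} (it depends on the presence of
#' RNA); called only with RNase, \code{shielded}. When the bait's IP
#' failed quality control in exactly one condition, RNA dependence cannot
#' be assessed and every prey called in the surviving condition is
#' \code{undetermined}. Baits failing both conditions are dropped.
#'
#' @param calls_minus,calls_plus HCIP call data frames (from
#'   [call_hcips()]) for the RNase-minus and RNase-plus conditions; either
#'   may be NULL when the condition failed QC.
#' @param qc_status The \code{status} data frame from [flag_failed_ips()].
#' @return Data frame with columns bait, prey, type.
#' @export
classify_rna_dependency <- function(calls_minus, calls_plus, qc_status) {
  passing <- function(calls) {
    if (is.null(calls) || !nrow(calls)) character(0)
    else unique(calls$prey[calls$pass])
  }
  baits <- unique(qc_status$bait)
  out <- list()
  for (b in baits) {
    ok_minus <- any(qc_status$pass[qc_status$bait == b &
                                     qc_status$condition == "rnase_minus"])
    ok_plus <- any(qc_status$pass[qc_status$bait == b &
                                    qc_status$condition == "rnase_plus"])
    if (!ok_minus && !ok_plus) next
    pm <- passing(if (is.null(calls_minus)) NULL
                  else calls_minus[calls_minus$bait == b, ])
    pp <- passing(if (is.null(calls_plus)) NULL
                  else calls_plus[calls_plus$bait == b, ])
    if (ok_minus && ok_plus) {
      preys <- union(pm, pp)
      if (!length(preys)) next
      type <- ifelse(preys %in% pm & preys %in% pp, "direct",
                     ifelse(preys %in% pm, "mediated", "shielded"))
    } else {
      preys <- if (ok_minus) pm else pp
      if (!length(preys)) next
      type <- rep("undetermined", length(preys))
    }
    out[[length(out) + 1L]] <- data.frame(bait = b, prey = preys,
                                          type = type,
                                          stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(bait = character(0), prey = character(0),
                      type = character(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Run HCIP calling and classification for every retained bait
#'
#' Applies [flag_failed_ips()], builds the per-condition background pools,
#' calls HCIPs for each bait x condition that passed quality control and
#' classifies the RNA dependency of every interaction.
#'
#' @param norm A \code{normalized_table}.
#' @param alpha Significance level, a scalar or a named per-bait vector.
#' @param ... Passed to [call_hcips()].
#' @return List with \code{edges} (bait, prey, type), \code{calls} (all
#'   per-condition HCIP calls) and \code{qc} (the [flag_failed_ips()]
#'   result).
#' @export
hcip_pipeline <- function(norm, alpha = 0.05, ...) {
  qc <- flag_failed_ips(norm)
  bg <- list(rnase_minus = background_pool(norm, "rnase_minus",
                                           qc$failed_samples),
             rnase_plus = background_pool(norm, "rnase_plus",
                                          qc$failed_samples))
  calls <- list(rnase_minus = NULL, rnase_plus = NULL)
  for (cond in names(calls)) {
    per_bait <- list()
    for (b in qc$retained_baits) {
      ok <- any(qc$status$pass[qc$status$bait == b &
                                 qc$status$condition == cond])
      if (!ok) next
      a <- if (length(alpha) > 1L) alpha[[b]] else alpha
      per_bait[[b]] <- call_hcips(norm, b, cond, bg[[cond]], alpha = a, ...)
    }
    if (length(per_bait)) calls[[cond]] <- do.call(rbind, per_bait)
  }
  edges <- classify_rna_dependency(calls$rnase_minus, calls$rnase_plus,
                                   qc$status)
  list(edges = edges, calls = calls, qc = qc)
}
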