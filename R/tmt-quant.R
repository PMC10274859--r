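#' TMT reporter-intensity table
#'
#' The raw-data container for the IP-MS arm of the pipeline: a protein x
#' sample matrix of non-negative reporter intensities (missing allowed)
#' plus a sample sheet describing each column, and optionally a per-protein
#' per-mix Top3 MS1 quantity used for MS1 apportioning.
#'
#' @param values Numeric matrix, proteins in rows (rownames required),
#'   samples in columns.
#' @param samples Data frame with one row per column of \code{values};
#'   required columns: \code{sample_id}, \code{mix}, \code{channel},
#'   \code{bait} (NA for controls), \code{condition} (\code{"rnase_plus"},
#'   \code{"rnase_minus"} or NA), \code{replicate}, \code{role}
#'   (\code{"bait_ip"}, \code{"igg"}, \code{"spike_in"}).
#' @param top3 Optional numeric matrix, proteins x mixes (column names =
#'   mix ids), of Top3 MS1 quantities.
#' @return An \code{intensity_table}.
#' @export
intensity_table <- function(values, samples, top3 = NULL) {
  stopifnot(is.matrix(values), !is.null(rownames(values)))
  req <- c("sample_id", "mix", "channel", "bait", "condition", "replicate", "role")
  if (!all(req %in% names(samples)))
    stop("sample sheet must have columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  if (nrow(samples) != ncol(values))
    stop("sample sheet rows must match matrix columns 1:1", call. = FALSE)
  if (anyDuplicated(samples$sample_id))
    stop("sample ids must be unique", call. = FALSE)
  colnames(values) <- samples$sample_id
  for (m in unique(samples$mix)) {
    sub <- samples[samples$mix == m, ]
    if (anyDuplicated(sub$channel))
      stop("channel labels must be unique within mix ", m, call. = FALSE)
    if (sum(sub$role == "spike_in") > 1L)
      stop("at most one spike_in per mix (mix ", m, ")", call. = FALSE)
  }
  if (any(values < 0, na.rm = TRUE))
    stop("reporter intensities must be non-negative", call. = FALSE)
  structure(list(values = values, samples = samples, top3 = top3,
                 stages = character(0)),
            class = "intensity_table")
}

#' @export
print.intensity_table <- function(x, ...) {
  cat(sprintf("Intensity table: %d proteins x %d samples, %d mixes\n",
              nrow(x$values), ncol(x$values), length(unique(x$samples$mix))))
  if (length(x$stages))
    cat("  stages applied:", paste(x$stages, collapse = " -> "), "\n")
  invisible(x)
}

.assert_stage <- function(table, needed, this) {
  if (this %in% table$stages)
    stop(sprintf("stage '%s' already applied", this), call. = FALSE)
  missing <- setdiff(needed, table$stages)
  if (length(missing))
    stop(sprintf("stage '%s' requires prior stage(s): %s", this,
                 paste(missing, collapse = ", ")), call. = FALSE)
  invisible(TRUE)
}

#' Apportion Top3 MS1 quantities over TMT reporter channels
#'
#' Mix-wise MS1-level correction: within each mix, a protein's channel
#' values are replaced by its Top3 MS1 quantity apportioned proportionally
#' to the reporter intensities, so the per-protein channel sum equals the
#' Top3 quantity. Rows whose reporters are all zero (or all missing) in a
#' mix become missing for that mix.
#'
#' @param raw An [intensity_table()] with \code{top3} present.
#' @return An \code{intensity_table} with stage \code{"apportion"} applied.
#' @export
apportion_ms1 <- function(raw) {
  stopifnot(inherits(raw, "intensity_table"))
  .assert_stage(raw, character(0), "apportion")
  if (is.null(raw$top3))
    stop("Top3 MS1 quantities are required for apportioning", call. = FALSE)
  out <- raw$values
  for (m in unique(raw$samples$mix)) {
    cols <- which(raw$samples$mix == m)
    block <- raw$values[, cols, drop = FALSE]
    rs <- rowSums(block, na.rm = TRUE)
    ok <- !is.na(rs) & rs > 0
    frac <- block / rs                     # NA rows / zero rows -> NaN
    top3 <- raw$top3[rownames(out), as.character(m)]
    out[, cols] <- frac * top3
    out[!ok, cols] <- NA_real_
  }
  raw$values <- out
  raw$stages <- c(raw$stages, "apportion")
  raw
}

#' Parts-per-million scaling and log2 transform
#'
#' Each sample column is rescaled so that its observed values sum to 1e6,
#' then a pseudocount of 1 is added and the values are log2 transformed.
#' Missing values stay missing; an all-missing column is left missing and
#' flagged.
#'
#' @param table An [intensity_table()].
#' @return The table with stage \code{"log2_ppm"} applied; all-missing
#'   columns are recorded in \code{attr(, "empty_samples")}.
#' @export
log2_ppm <- function(table) {
  stopifnot(inherits(table, "intensity_table"))
  .assert_stage(table, character(0), "log2_ppm")
  v <- table$values
  sums <- colSums(v, na.rm = TRUE)
  empty <- colSums(!is.na(v)) == 0L
  scale <- ifelse(empty | sums == 0, NA_real_, 1e6 / sums)
  v <- sweep(v, 2L, scale, `*`)
  table$values <- log2(v + 1)
  table$stages <- c(table$stages, "log2_ppm")
  attr(table, "empty_samples") <- colnames(v)[empty]
  table
}

#' Within-mix batch correction
#'
#' For each non-spike sample, the protein-wise mean over the *other*
#' non-spike samples of the same mix is subtracted. The spike-in sample
#' (which pools RNase-treated and untreated material) is corrected by the
#' mean over the entire rest of the mix. Missing values are excluded from
#' the means.
#'
#' @param table A log2-ppm [intensity_table()].
#' @return The table with stage \code{"batch"} applied.
#' @export
batch_correct <- function(table) {
  stopifnot(inherits(table, "intensity_table"))
  .assert_stage(table, "log2_ppm", "batch")
  v <- table$values
  out <- v
  for (m in unique(table$samples$mix)) {
    cols <- which(table$samples$mix == m)
    if (length(cols) < 2L)
      stop("cannot batch-correct a mix with a single sample (mix ", m, ")",
           call. = FALSE)
    spike <- cols[table$samples$role[cols] == "spike_in"]
    nonspike <- setdiff(cols, spike)
    for (j in cols) {
      ref <- if (j %in% spike) setdiff(cols, j) else setdiff(nonspike, j)
      out[, j] <- v[, j] - rowMeans(v[, ref, drop = FALSE], na.rm = TRUE)
    }
  }
  out[is.nan(out)] <- NA_real_
  table$values <- out
  table$stages <- c(table$stages, "batch")
  table
}

#' Per-sample z-scoring
#'
#' Each sample column is standardized across its observed proteins using
#' the sample standard deviation (n - 1). Constant columns become all
#' zeros and are flagged.
#'
#' @param table A batch-corrected [intensity_table()].
#' @return A \code{normalized_table}: the same structure with stage
#'   \code{"zscore"} applied and constant columns in
#'   \code{attr(, "constant_samples")}.
#' @export
zscore_samples <- function(table) {
  stopifnot(inherits(table, "intensity_table"))
  .assert_stage(table, "batch", "zscore")
  v <- table$values
  mu <- colMeans(v, na.rm = TRUE)
  sd_ <- apply(v, 2L, stats::sd, na.rm = TRUE)
  const <- !is.na(sd_) & sd_ == 0
  centred <- sweep(v, 2L, mu, `-`)
  z <- sweep(centred, 2L, ifelse(const, 1, sd_), `/`)
  z[, const] <- 0 * v[, const]             # keep NA pattern, zero elsewhere
  if (any(const))
    warning("constant sample column(s) set to zero: ",
            paste(colnames(v)[const], collapse = ", "), call. = FALSE)
  table$values <- z
  table$stages <- c(table$stages, "zscore")
  attr(table, "constant_samples") <- colnames(v)[const]
  class(table) <- c("normalized_table", class(table))
  table
}

#' Normalize a raw reporter table through the full chain
#'
#' Convenience wrapper applying [apportion_ms1()] (when Top3 MS1 values are
#' present), [log2_ppm()], [batch_correct()] and [zscore_samples()] in that
#' fixed order.
#'
#' @param raw An [intensity_table()].
#' @return A \code{normalized_table}.
#' @export
normalize_tmt <- function(raw) {
  if (!is.null(raw$top3)) raw <- apportion_ms1(raw)
  zscore_samples(batch_correct(log2_ppm(raw)))
}

#' Flag failed IPs
#'
#' A bait x condition IP set fails when the bait protein itself is not
#' enriched within the top tail of measured proteins (z > \code{z_threshold}
#' in at least 2 replicates is required to pass) or when a replicate is too
#' sparse (fewer quantified proteins than \code{sparsity_frac} times the
#' median of its mix). Failed IP sets are removed from interactor calling
#' and routed to the background pool. A retained bait needs at least two
#' replicates in at least one condition.
#'
#' @param norm A \code{normalized_table}.
#' @param z_threshold Per-sample z-score cutoff for bait self-enrichment
#'   (default 1.645, the upper 5% tail of a standard normal).
#' @param sparsity_frac Minimum fraction of the mix-median quantified
#'   protein count a replicate must reach.
#' @return A list: \code{status} (data.frame bait x condition with
#'   \code{pass} and \code{reason}), \code{failed_samples} (sample ids
#'   routed to background), \code{retained_baits}.
#' @export
flag_failed_ips <- function(norm, z_threshold = 1.645, sparsity_frac = 0.5) {
  stopifnot(inherits(norm, "normalized_table"))
  ss <- norm$samples
  v <- norm$values
  nquant <- colSums(!is.na(v))
  mix_median <- tapply(nquant, ss$mix, stats::median)
  sparse <- nquant < sparsity_frac * mix_median[as.character(ss$mix)]

  ips <- ss[ss$role == "bait_ip", ]
  keys <- unique(ips[, c("bait", "condition")])
  status <- data.frame(bait = keys$bait, condition = keys$condition,
                       pass = NA, reason = "", stringsAsFactors = FALSE)
  failed_samples <- character(0)
  for (i in seq_len(nrow(status))) {
    b <- status$bait[i]; cond <- status$condition[i]
    cols <- which(ss$role == "bait_ip" & ss$bait == b & ss$condition == cond)
    ok_cols <- cols[!sparse[cols]]
    if (!b %in% rownames(v)) {
      status$pass[i] <- FALSE; status$reason[i] <- "bait unmeasured"
    } else if (length(ok_cols) < 2L) {
      status$pass[i] <- FALSE; status$reason[i] <- "too sparse"
    } else {
      z <- v[b, ok_cols]
      n_enriched <- sum(!is.na(z) & z > z_threshold)
      if (n_enriched < 2L) {
        status$pass[i] <- FALSE; status$reason[i] <- "bait not enriched"
      } else {
        status$pass[i] <- TRUE; status$reason[i] <- "ok"
      }
    }
    if (!status$pass[i])
      failed_samples <- c(failed_samples, ss$sample_id[cols])
  }
  pass_by_bait <- tapply(status$pass, status$bait, any)
  retained <- names(pass_by_bait)[pass_by_bait]
  list(status = status, failed_samples = failed_samples,
       retained_baits = retained)
}
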