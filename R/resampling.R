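#' Fraction of edges supported by a reference pair set
#'
#' @param edges Data frame/matrix of unordered pairs (first two columns).
#' @param reference Data frame/matrix of unordered reference pairs.
#' @return The supported fraction F_exp = |edges intersect reference| /
#'   |edges|.
#' @export
support_fraction <- function(edges, reference) {
  e <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (!nrow(e)) stop("empty edge set", call. = FALSE)
  ref <- as.data.frame(reference, stringsAsFactors = FALSE)
  rkeys <- if (nrow(ref)) unique(pair_key(ref[[1]], ref[[2]])) else character(0)
  mean(pair_key(e[[1]], e[[2]]) %in% rkeys)
}

#' Resampling test for reference support of a network
#'
#' Compares the observed supported fraction F_exp of a set of interactions
#' against the distribution { F_i } of supported fractions of resampled
#' networks. In \code{bait_degree_preserving} mode, for every bait the
#' same number of random preys as observed is drawn uniformly without
#' replacement from the sampling universe and paired with the bait
#' (degrees are preserved; draws are independent across baits). In
#' \code{all_pairs} mode, |edges| uniform random pairs are drawn from the
#' universe. The one-sided empirical p-value uses the add-one estimator
#' \eqn{p = (1 + \#\{F_i \ge F_{exp}\}) / (1 + n)} so it is never zero.
#'
#' @param edges Data frame with columns bait, prey (bait mode) or any two
#'   protein columns (all_pairs mode).
#' @param reference Reference pair list (unordered).
#' @param universe Character vector of proteins to sample from.
#' @param mode \code{"bait_degree_preserving"} or \code{"all_pairs"}.
#' @param n Number of resamples (1000 by default; 10000 for tighter p).
#' @param seed Integer seed.
#' @return A \code{resampling_result}: list with F_exp, F_samples, n,
#'   p_value, fold (F_exp / mean(F_i)), mode, universe_size.
#' @export
resample_null <- function(edges, reference, universe,
                          mode = c("bait_degree_preserving", "all_pairs"),
                          n = 1000L, seed = 1L) {
  mode <- match.arg(mode)
  e <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (!nrow(e)) stop("empty edge set", call. = FALSE)
  universe <- unique(universe)
  f_exp <- support_fraction(e, reference)
  ref <- as.data.frame(reference, stringsAsFactors = FALSE)
  rkeys <- if (nrow(ref)) unique(pair_key(ref[[1]], ref[[2]])) else character(0)

  set.seed(seed)
  if (mode == "bait_degree_preserving") {
    if (!all(c("bait", "prey") %in% names(e)))
      stop("bait mode requires columns 'bait' and 'prey'", call. = FALSE)
    degree <- table(e$bait)
    if (max(degree) > length(universe) - 1L)
      stop("universe smaller than the largest per-bait degree", call. = FALSE)
    baits <- names(degree)
    f_i <- vapply(seq_len(n), function(i) {
      keys <- unlist(lapply(baits, function(b) {
        rp <- sample(setdiff(universe, b), degree[[b]])
        pair_key(rep(b, length(rp)), rp)
      }))
      mean(keys %in% rkeys)
    }, numeric(1))
  } else {
    n_edges <- nrow(e)
    f_i <- vapply(seq_len(n), function(i) {
      a <- sample(universe, n_edges, replace = TRUE)
      b <- sample(universe, n_edges, replace = TRUE)
      while (any(a == b)) {
        idx <- a == b
        b[idx] <- sample(universe, sum(idx), replace = TRUE)
      }
      mean(pair_key(a, b) %in% rkeys)
    }, numeric(1))
  }
  p <- (1 + sum(f_i >= f_exp)) / (1 + n)
  structure(list(F_exp = f_exp, F_samples = f_i, n = n, p_value = p,
                 fold = if (mean(f_i) > 0) f_exp / mean(f_i) else NA_real_,
                 mode = mode, universe_size = length(universe)),
            class = "resampling_result")
}

#' @export
print.resampling_result <- function(x, ...) {
  cat(sprintf("Resampling test (%s, n = %d, universe %d):\n", x$mode, x$n,
              x$universe_size))
  cat(sprintf("  F_exp = %.4f, mean F_i = %.4f, fold = %.2f, p = %.4g\n",
              x$F_exp, mean(x$F_samples), x$fold, x$p_value))
  invisible(x)
}

#' Summarize resampling results across strata
#'
#' @param results Named list of \code{resampling_result} objects (e.g. one
#'   per interaction type x reference).
#' @return Data frame: stratum, F_exp, mean_F_i, fold, p_value, n.
#' @export
resampling_summary <- function(results) {
  stopifnot(length(results) > 0)
  do.call(rbind, lapply(names(results), function(nm) {
    r <- results[[nm]]
    data.frame(stratum = nm, F_exp = r$F_exp, mean_F_i = mean(r$F_samples),
               fold = r$fold, p_value = r$p_value, n = r$n,
               stringsAsFactors = FALSE)
  }))
}
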