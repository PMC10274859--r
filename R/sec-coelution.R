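#' Average SEC replicates into one elution matrix
#'
#' Cellwise mean over observed replicates (missing values removed from the
#' mean); a cell missing in every replicate stays missing.
#'
#' @param replicates List of protein x fraction matrices with identical
#'   dimnames (e.g. from [simulate_sec()]).
#' @return A single elution matrix; the calibration attribute, if present
#'   on the list, is carried over.
#' @export
average_sec_replicates <- function(replicates) {
  stopifnot(is.list(replicates), length(replicates) >= 1L)
  dn <- dimnames(replicates[[1]])
  for (r in replicates)
    if (!identical(dimnames(r), dn))
      stop("replicate matrices must share protein and fraction axes",
           call. = FALSE)
  sums <- Reduce(`+`, lapply(replicates, function(m) ifelse(is.na(m), 0, m)))
  nobs <- Reduce(`+`, lapply(replicates, function(m) !is.na(m)))
  out <- sums / nobs
  out[nobs == 0L] <- NA_real_
  dimnames(out) <- dn
  attr(out, "calibration") <- attr(replicates, "calibration")
  out
}

#' Detect elution peaks in one profile
#'
#' Local maxima of a moving-average smoothed profile (window 3) exceeding
#' a noise floor of \code{max(min_intensity, k * median(observed))}.
#' Maxima closer than \code{min_separation} fractions are merged, keeping
#' the higher one.
#'
#' @param profile Numeric vector over fractions (names = fraction labels;
#'   missing treated as zero signal for smoothing).
#' @param min_intensity Absolute noise floor.
#' @param k Multiple of the median observed intensity forming the relative
#'   noise floor.
#' @param min_separation Minimum fraction distance between reported peaks.
#' @return Integer vector of apex fraction labels (empty when flat).
#' @export
detect_peaks <- function(profile, min_intensity = 0, k = 2,
                         min_separation = 3L) {
  if (sum(!is.na(profile)) < 5L) return(integer(0))
  labels <- as.integer(names(profile))
  x <- ifelse(is.na(profile), 0, profile)
  n <- length(x)
  sm <- as.numeric(stats::filter(x, rep(1 / 3, 3), sides = 2))
  sm[1] <- mean(x[1:2]); sm[n] <- mean(x[(n - 1):n])
  floor_ <- max(min_intensity, k * stats::median(profile, na.rm = TRUE), 0)
  if (all(sm <= floor_)) return(integer(0))
  is_peak <- logical(n)
  for (i in seq_len(n)) {
    left <- if (i > 1L) sm[i - 1L] else -Inf
    right <- if (i < n) sm[i + 1L] else -Inf
    is_peak[i] <- sm[i] > floor_ && sm[i] >= left && sm[i] > right
  }
  idx <- which(is_peak)
  if (!length(idx)) return(integer(0))
  # merge peaks closer than min_separation, keeping the higher
  idx <- idx[order(-sm[idx])]
  kept <- integer(0)
  for (i in idx)
    if (!length(kept) || all(abs(labels[i] - labels[kept]) >= min_separation))
      kept <- c(kept, i)
  sort(labels[kept])
}

#' Co-elution score for one protein pair
#'
#' When the two peak lists contain apexes within \code{max_apex_dist}
#' fractions of each other, the score is the Pearson correlation of the
#' two profiles over a +/- \code{window} fraction window centred on the
#' mean apex; otherwise there is no shared peak and no call. Windows with
#' fewer than 3 mutually observed fractions yield no call.
#'
#' @param a,b Protein ids.
#' @param matrix An elution matrix (see [average_sec_replicates()]).
#' @param peaks Optional named list of precomputed [detect_peaks()]
#'   results, for caching.
#' @param max_apex_dist Maximum apex distance counted as shared.
#' @param window Half-width of the correlation window in fractions.
#' @param ... Passed to [detect_peaks()].
#' @return List with \code{score} (NA when no call) and \code{apex}
#'   (shared apex fraction, NA when none).
#' @export
coelution_score <- function(a, b, matrix, peaks = NULL,
                            max_apex_dist = 2L, window = 5L, ...) {
  stopifnot(a %in% rownames(matrix), b %in% rownames(matrix))
  get_peaks <- function(p) {
    if (!is.null(peaks)) peaks[[p]]
    else detect_peaks(matrix[p, ], ...)
  }
  pa <- get_peaks(a); pb <- get_peaks(b)
  if (!length(pa) || !length(pb))
    return(list(score = NA_real_, apex = NA_integer_))
  d <- abs(outer(pa, pb, `-`))
  if (min(d) > max_apex_dist)
    return(list(score = NA_real_, apex = NA_integer_))
  hit <- which(d == min(d), arr.ind = TRUE)[1L, ]
  apex <- round((pa[hit[1]] + pb[hit[2]]) / 2)
  labels <- as.integer(colnames(matrix))
  sel <- which(labels >= apex - window & labels <= apex + window)
  xa <- matrix[a, sel]; xb <- matrix[b, sel]
  ok <- !is.na(xa) & !is.na(xb)
  if (sum(ok) < 3L || stats::sd(xa[ok]) == 0 || stats::sd(xb[ok]) == 0)
    return(list(score = NA_real_, apex = NA_integer_))
  list(score = stats::cor(xa[ok], xb[ok]), apex = as.integer(apex))
}

#' Decoy-calibrated co-elution calls
#'
#' Scores every candidate pair, builds a decoy score distribution from
#' random co-measured protein pairs outside the candidate set (scored
#' identically; pairs without a shared peak score as no-call and rank
#' below every real score), converts each candidate score to an empirical
#' p-value \eqn{p = (1 + \#\{decoy \ge score\}) / (1 + n_{decoys})},
#' adjusts by Benjamini-Hochberg and calls pairs at q < \code{q_cutoff}
#' that have a shared peak.
#'
#' @param candidate_pairs Data frame or 2-column matrix of protein pairs.
#' @param matrix Elution matrix.
#' @param n_decoys Number of decoy pairs (>= 100).
#' @param seed Integer seed for decoy sampling.
#' @param q_cutoff q-value call threshold (default 0.1).
#' @param ... Passed to [coelution_score()].
#' @return Data frame with columns a, b, apex_fraction, score, p_value,
#'   q_value, called.
#' @export
decoy_qvalues <- function(candidate_pairs, matrix, n_decoys = 1000L,
                          seed = 1L, q_cutoff = 0.1, ...) {
  if (n_decoys < 100L)
    stop("insufficient decoys: need at least 100", call. = FALSE)
  cand <- as.data.frame(candidate_pairs, stringsAsFactors = FALSE)
  names(cand)[1:2] <- c("a", "b")
  measured <- rownames(matrix)[rowSums(!is.na(matrix)) >= 5L]
  cand <- cand[cand$a %in% measured & cand$b %in% measured, , drop = FALSE]
  if (!nrow(cand)) stop("no candidate pair is co-measured", call. = FALSE)

  peaks <- lapply(stats::setNames(nm = measured),
                  function(p) detect_peaks(matrix[p, ]))
  score_pair <- function(a, b) coelution_score(a, b, matrix, peaks = peaks, ...)

  target <- mapply(function(a, b) score_pair(a, b), cand$a, cand$b,
                   SIMPLIFY = FALSE)
  t_score <- vapply(target, `[[`, numeric(1), "score")
  t_apex <- vapply(target, function(s) as.integer(s$apex), integer(1))

  set.seed(seed)
  cand_keys <- pair_key(cand$a, cand$b)
  decoy_scores <- numeric(0)
  guard <- 0L
  while (length(decoy_scores) < n_decoys && guard < 50L) {
    need <- n_decoys - length(decoy_scores)
    da <- sample(measured, 2L * need + 10L, replace = TRUE)
    db <- sample(measured, 2L * need + 10L, replace = TRUE)
    ok <- da != db & !(pair_key(da, db) %in% cand_keys)
    da <- da[ok]; db <- db[ok]
    take <- seq_len(min(need, length(da)))
    decoy_scores <- c(decoy_scores, mapply(
      function(a, b) score_pair(a, b)$score, da[take], db[take]))
    guard <- guard + 1L
  }
  decoy_scores <- decoy_scores[seq_len(n_decoys)]
  d_rank <- ifelse(is.na(decoy_scores), -Inf, decoy_scores)
  t_rank <- ifelse(is.na(t_score), -Inf, t_score)
  p <- vapply(t_rank, function(s) (1 + sum(d_rank >= s)) / (1 + n_decoys),
              numeric(1))
  q <- stats::p.adjust(p, method = "BH")
  data.frame(a = cand$a, b = cand$b, apex_fraction = t_apex,
             score = t_score, p_value = p, q_value = q,
             called = !is.na(t_score) & q < q_cutoff,
             stringsAsFactors = FALSE, row.names = NULL)
}
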