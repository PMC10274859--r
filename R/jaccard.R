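#' Binding-site set for one RNA-binding protein
#'
#' @param rbp Protein id.
#' @param sites Character vector of unique window identifiers.
#' @param cell_context Label of the cell context the sites were mapped in.
#' @return A \code{binding_site_set}.
#' @export
binding_site_set <- function(rbp, sites, cell_context = "default") {
  structure(list(rbp = rbp, sites = unique(as.character(sites)),
                 cell_context = cell_context),
            class = "binding_site_set")
}

#' Jaccard index of two binding-site sets
#'
#' |A intersect B| / |A union B|. Undefined (NA) when both sets are
#' empty; an error when the sets come from different cell contexts.
#'
#' @param A,B \code{binding_site_set} objects (or plain character
#'   vectors, in which case no context check is done).
#' @return A value in [0, 1], or NA.
#' @export
jaccard_index <- function(A, B) {
  if (inherits(A, "binding_site_set") && inherits(B, "binding_site_set")) {
    if (!identical(A$cell_context, B$cell_context))
      stop("cell context mismatch: ", A$cell_context, " vs ", B$cell_context,
           call. = FALSE)
    A <- A$sites; B <- B$sites
  }
  A <- unique(A); B <- unique(B)
  u <- length(union(A, B))
  if (u == 0L) return(NA_real_)
  length(intersect(A, B)) / u
}

#' Simulate binding-site sets coupled to the interaction network
#'
#' Every protein first draws a private site set (each window included
#' with probability \code{baseline_site_rate}). Then, for every true
#' edge, the second partner inherits the first partner's occupancy state
#' at each window with probability \code{overlap_rho[type]}, so
#' interacting pairs share sites beyond the random-overlap baseline and
#' the expected sharing increases with rho. With rho = 1 the partner's
#' set becomes an exact copy (Jaccard 1); with rho = 0 sets stay
#' independent and the expected Jaccard is the closed-form baseline
#' p / (2 - p) for inclusion probability p.
#'
#' @param truth A [make_truth()] result.
#' @param config The matching [sim_config()].
#' @return Named list of [binding_site_set()] objects, one per protein,
#'   with the window coordinate table in \code{attr(, "windows")}
#'   (0-based half-open, BED-exportable).
#' @export
simulate_binding_sites <- function(truth, config) {
  stopifnot(inherits(truth, "synthetic_truth"), inherits(config, "sim_config"))
  set.seed(config$seed + 4L)
  n_w <- config$site_universe
  windows <- data.frame(
    chrom = "chrS", start = (seq_len(n_w) - 1L) * 100L,
    end = seq_len(n_w) * 100L,
    name = sprintf("W%05d", seq_len(n_w)),
    score = 0L, strand = "+", stringsAsFactors = FALSE)
  proteins <- truth$proteins
  occ <- matrix(stats::runif(length(proteins) * n_w) < config$baseline_site_rate,
                length(proteins), n_w, dimnames = list(proteins, windows$name))
  for (i in seq_len(nrow(truth$edges))) {
    e <- truth$edges[i, ]
    rho <- config$overlap_rho[[e$type]]
    if (rho <= 0) next
    copy <- stats::runif(n_w) < rho
    occ[e$prey, copy] <- occ[e$bait, copy]
  }
  sets <- lapply(stats::setNames(nm = proteins), function(p)
    binding_site_set(p, windows$name[occ[p, ]]))
  attr(sets, "windows") <- windows
  sets
}

#' Export a binding-site set to BED
#'
#' Writes the six-column BED (chrom, start, end, name, score, strand) for
#' the windows in the set, using GenomicRanges/rtracklayer.
#'
#' @param set A [binding_site_set()].
#' @param windows Window coordinate table (see
#'   [simulate_binding_sites()]).
#' @param file Output path.
#' @return The file path, invisibly.
#' @export
export_bed <- function(set, windows, file) {
  if (!requireNamespace("GenomicRanges", quietly = TRUE) ||
      !requireNamespace("rtracklayer", quietly = TRUE))
    stop("BED export requires GenomicRanges and rtracklayer", call. = FALSE)
  w <- windows[windows$name %in% set$sites, , drop = FALSE]
  gr <- GenomicRanges::GRanges(
    seqnames = w$chrom,
    ranges = IRanges::IRanges(start = w$start + 1L, end = w$end),
    strand = w$strand, name = w$name, score = w$score)
  rtracklayer::export(gr, file, format = "BED")
  invisible(file)
}

#' Compare Jaccard indices of interaction types against random RBP pairs
#'
#' Computes the Jaccard index for every network pair whose two proteins
#' have binding-site sets, grouped by RNA-dependency type, and compares
#' each type's distribution against random non-interacting RBP pairs with
#' a one-sided rank-sum test (greater).
#'
#' @param net A \code{ppi_network}.
#' @param site_sets Named list of [binding_site_set()] objects.
#' @param n_random Number of random pairs.
#' @param seed Integer seed.
#' @return List with \code{by_type} (named list of Jaccard vectors),
#'   \code{random} (Jaccard vector), \code{tests} (data.frame: type,
#'   n, median, median_random, p_value).
#' @export
typewise_jaccard_comparison <- function(net, site_sets, n_random = 500L,
                                        seed = 1L) {
  stopifnot(inherits(net, "ppi_network"))
  with_sites <- names(site_sets)
  e <- net$edges[!is.na(net$edges$ip_type) &
                   net$edges$a %in% with_sites &
                   net$edges$b %in% with_sites, , drop = FALSE]
  by_type <- lapply(split(e, e$ip_type), function(sub)
    mapply(function(a, b) jaccard_index(site_sets[[a]], site_sets[[b]]),
           sub$a, sub$b))
  set.seed(seed)
  net_keys <- pair_key(net$edges$a, net$edges$b)
  random <- numeric(0)
  guard <- 0L
  while (length(random) < n_random && guard < 50L) {
    a <- sample(with_sites, 2L * (n_random - length(random)) + 10L,
                replace = TRUE)
    b <- sample(with_sites, length(a), replace = TRUE)
    ok <- a != b & !(pair_key(a, b) %in% net_keys)
    if (!any(ok) && guard > 5L)
      stop("no eligible random pairs", call. = FALSE)
    a <- a[ok]; b <- b[ok]
    take <- seq_len(min(n_random - length(random), length(a)))
    random <- c(random, mapply(function(x, y)
      jaccard_index(site_sets[[x]], site_sets[[y]]), a[take], b[take]))
    guard <- guard + 1L
  }
  tests <- do.call(rbind, lapply(names(by_type), function(t) {
    x <- by_type[[t]][!is.na(by_type[[t]])]
    data.frame(type = t, n = length(x), median = stats::median(x),
               median_random = stats::median(random, na.rm = TRUE),
               p_value = if (length(x)) rank_sum_p(x, random[!is.na(random)])
                         else NA_real_,
               stringsAsFactors = FALSE)
  }))
  list(by_type = by_type, random = random, tests = tests)
}

#' All-pairs Jaccard matrix over binding-site sets
#'
#' @param site_sets Named list of [binding_site_set()] objects.
#' @return Symmetric matrix of Jaccard indices (diagonal 1 for non-empty
#'   sets, NA where undefined).
#' @export
jaccard_matrix <- function(site_sets) {
  n <- length(site_sets)
  nm <- names(site_sets)
  J <- matrix(NA_real_, n, n, dimnames = list(nm, nm))
  for (i in seq_len(n)) for (j in i:n)
    J[i, j] <- J[j, i] <- jaccard_index(site_sets[[i]], site_sets[[j]])
  J
}

#' Cluster a Jaccard matrix
#'
#' Average-linkage agglomerative clustering on the distance 1 - J.
#'
#' @param J Symmetric Jaccard matrix.
#' @param k Number of clusters (default 2; ignored for a 1 x 1 matrix).
#' @return List with \code{order} (display order), \code{cluster} (named
#'   membership vector), \code{hclust} (NULL for a singleton).
#' @export
cluster_jaccard_matrix <- function(J, k = 2L) {
  stopifnot(is.matrix(J), nrow(J) == ncol(J))
  if (nrow(J) == 1L)
    return(list(order = rownames(J),
                cluster = stats::setNames(1L, rownames(J)), hclust = NULL))
  d <- stats::as.dist(1 - ifelse(is.na(J), 0, J))
  hc <- stats::hclust(d, method = "average")
  cl <- stats::cutree(hc, k = min(k, nrow(J)))
  list(order = rownames(J)[hc$order], cluster = cl, hclust = hc)
}
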