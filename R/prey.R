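#' Internal: directed bait -> prey links from edge provenance
#'
#' @param net A \code{ppi_network}.
#' @return Data frame with columns bait, prey (unique rows).
#' @keywords internal
bait_prey_links <- function(net) {
  e <- net$edges[net$edges$source_baits != "", , drop = FALSE]
  if (!nrow(e))
    return(data.frame(bait = character(0), prey = character(0),
                      stringsAsFactors = FALSE))
  links <- do.call(rbind, lapply(seq_len(nrow(e)), function(i) {
    baits <- strsplit(e$source_baits[i], ";", fixed = TRUE)[[1]]
    preys <- lapply(baits, function(b) setdiff(c(e$a[i], e$b[i]), b))
    keep <- lengths(preys) == 1L
    data.frame(bait = baits[keep], prey = unlist(preys[keep]),
               stringsAsFactors = FALSE)
  }))
  unique(links)
}

#' Prey life-cycle step profiles
#'
#' For every prey (any node interacting with at least one bait, including
#' baits captured as preys of other baits), the fraction of its
#' interacting baits falling in each life-cycle step. All interaction
#' types count. Baits without a step label accumulate in an
#' \code{"unknown"} bin.
#'
#' @param net A \code{ppi_network} with IP edges.
#' @param bait_steps Named character vector: step per bait (may contain
#'   "unknown").
#' @return List with \code{profiles} (prey x step fraction matrix, rows
#'   sum to 1) and \code{info} (data.frame: prey, n_baits, n_steps,
#'   multi_step).
#' @export
prey_step_profiles <- function(net, bait_steps) {
  stopifnot(inherits(net, "ppi_network"))
  links <- bait_prey_links(net)
  step_of <- function(b) {
    s <- bait_steps[b]
    ifelse(is.na(s), "unknown", s)
  }
  links$step <- step_of(links$bait)
  steps <- sort(unique(links$step))
  preys <- sort(unique(links$prey))
  profiles <- matrix(0, length(preys), length(steps),
                     dimnames = list(preys, steps))
  tab <- table(links$prey, links$step)
  profiles[rownames(tab), colnames(tab)] <- tab
  n_baits <- rowSums(profiles)
  profiles <- profiles / n_baits
  n_steps <- rowSums(profiles > 0)
  info <- data.frame(prey = preys, n_baits = as.integer(n_baits),
                     n_steps = as.integer(n_steps),
                     multi_step = n_steps >= 2L, stringsAsFactors = FALSE)
  list(profiles = profiles, info = info)
}

#' Cluster prey profiles and assign dominant steps
#'
#' Agglomerative clustering (average linkage, Euclidean distance) of the
#' step-fraction profiles; each cluster is labelled with the argmax of its
#' mean profile.
#'
#' @param profiles Prey x step fraction matrix (from
#'   [prey_step_profiles()]).
#' @param k Number of clusters (alternative: \code{h}, a cut height).
#' @param h Cut height, used when \code{k} is NULL.
#' @return List with \code{cluster} (named integer vector),
#'   \code{cluster_step} (dominant step per cluster), \code{prey_step}
#'   (dominant step per prey via its cluster), \code{hclust}.
#' @export
assign_prey_steps <- function(profiles, k = NULL, h = NULL) {
  if (nrow(profiles) < 2L)
    stop("need at least 2 profiles", call. = FALSE)
  if (!is.null(k) && k > nrow(profiles))
    stop("k exceeds the number of profiles", call. = FALSE)
  hc <- stats::hclust(stats::dist(profiles), method = "average")
  cl <- if (!is.null(k)) stats::cutree(hc, k = k)
  else if (!is.null(h)) stats::cutree(hc, h = h)
  else stats::cutree(hc, k = min(ncol(profiles), nrow(profiles)))
  cluster_step <- vapply(sort(unique(cl)), function(g) {
    mp <- colMeans(profiles[cl == g, , drop = FALSE])
    names(mp)[which.max(mp)]
  }, character(1))
  names(cluster_step) <- sort(unique(cl))
  list(cluster = cl, cluster_step = cluster_step,
       prey_step = stats::setNames(cluster_step[as.character(cl)], names(cl)),
       hclust = hc)
}

#' Prey x bait binary incidence matrix
#'
#' 1 when any interaction type links the prey to the bait.
#'
#' @param net A \code{ppi_network} with IP edges.
#' @return Binary matrix, preys in rows, baits in columns.
#' @export
prey_incidence <- function(net) {
  stopifnot(inherits(net, "ppi_network"))
  links <- bait_prey_links(net)
  preys <- sort(unique(links$prey)); baits <- sort(unique(links$bait))
  inc <- matrix(0L, length(preys), length(baits),
                dimnames = list(preys, baits))
  inc[cbind(match(links$prey, preys), match(links$bait, baits))] <- 1L
  inc
}

#' Prey-prey Pearson correlation over bait incidence
#'
#' Pearson correlation of every pair of prey incidence vectors across the
#' bait axis. Constant rows (a prey interacting with every bait, or an
#' all-zero row) have no defined correlation and are masked as NA. For
#' display, rows are ordered by average-linkage clustering on the
#' distance 1 - r.
#'
#' @param incidence Prey x bait matrix from [prey_incidence()].
#' @return List with \code{r} (symmetric correlation matrix, NA where
#'   undefined), \code{order} (display order of the defined rows).
#' @export
prey_correlation_matrix <- function(incidence) {
  if (ncol(incidence) < 2L)
    stop("need at least 2 baits", call. = FALSE)
  r <- suppressWarnings(stats::cor(t(incidence)))
  defined <- apply(incidence, 1L, function(x) stats::sd(x) > 0)
  r[!defined, ] <- NA_real_; r[, !defined] <- NA_real_
  diag(r)[defined] <- 1
  ord <- rownames(incidence)
  if (sum(defined) >= 2L) {
    sub <- r[defined, defined]
    d <- stats::as.dist(1 - ifelse(is.na(sub), 0, sub))
    hc <- stats::hclust(d, method = "average")
    ord <- c(rownames(sub)[hc$order], rownames(incidence)[!defined])
  }
  list(r = r, order = ord)
}
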