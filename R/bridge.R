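#' Internal: adjacency-list graph from assorted inputs
#'
#' Accepts a \code{ppi_network}, a two-column data frame/matrix of edges,
#' or an already-built adjacency structure. The graph is treated as
#' simple and undirected; self loops and duplicate pairs are collapsed.
#'
#' @param graph Network, edge list or adjacency structure.
#' @return List with \code{nodes} (character) and \code{adj} (list of
#'   integer neighbour vectors).
#' @keywords internal
as_adjacency <- function(graph) {
  if (is.list(graph) && !is.null(graph$adj) && !is.null(graph$nodes) &&
      !inherits(graph, "ppi_network"))
    return(graph)
  e <- if (inherits(graph, "ppi_network")) graph$edges[, c("a", "b")]
  else as.data.frame(graph, stringsAsFactors = FALSE)[, 1:2]
  names(e) <- c("a", "b")
  e <- e[e$a != e$b, , drop = FALSE]
  keys <- pair_key(e$a, e$b)
  e <- e[!duplicated(keys), , drop = FALSE]
  nodes <- sort(unique(c(e$a, e$b)))
  ai <- match(e$a, nodes); bi <- match(e$b, nodes)
  adj <- vector("list", length(nodes))
  for (i in seq_along(nodes)) adj[[i]] <- integer(0)
  for (k in seq_along(ai)) {
    adj[[ai[k]]] <- c(adj[[ai[k]]], bi[k])
    adj[[bi[k]]] <- c(adj[[bi[k]]], ai[k])
  }
  list(nodes = nodes, adj = adj)
}

#' Internal: BFS distances and shortest-path counts from one source
#'
#' Layered breadth-first counting: \code{sigma[v]} is the number of
#' distinct shortest paths from the source to \code{v}.
#'
#' @param g Adjacency structure from [as_adjacency()].
#' @param src Integer source index.
#' @return List with integer \code{dist} (NA when unreachable) and
#'   numeric \code{sigma}.
#' @keywords internal
bfs_counts <- function(g, src) {
  n <- length(g$nodes)
  dist <- rep(NA_integer_, n)
  sigma <- numeric(n)
  dist[src] <- 0L; sigma[src] <- 1
  frontier <- src
  while (length(frontier)) {
    nxt <- integer(0)
    for (v in frontier) {
      for (w in g$adj[[v]]) {
        if (is.na(dist[w])) {
          dist[w] <- dist[v] + 1L
          nxt <- c(nxt, w)
        }
        if (dist[w] == dist[v] + 1L)
          sigma[w] <- sigma[w] + sigma[v]
      }
    }
    frontier <- unique(nxt)
  }
  list(dist = dist, sigma = sigma)
}

#' Shortest-path counts between two nodes
#'
#' Counts the shortest paths between \code{s} and \code{t} and, for every
#' other node \code{v}, the number of those paths on which \code{v} is an
#' interior node (endpoints never count for themselves). Unreachable
#' pairs have zero paths.
#'
#' @param graph Network, edge list or adjacency structure.
#' @param s,t Node names.
#' @return List with \code{sigma} (number of shortest s-t paths) and
#'   \code{through} (named vector of per-node interior counts).
#' @export
shortest_path_counts <- function(graph, s, t) {
  g <- as_adjacency(graph)
  si <- match(s, g$nodes); ti <- match(t, g$nodes)
  if (is.na(si) || is.na(ti))
    stop("node not in graph: ", paste(setdiff(c(s, t), g$nodes),
                                      collapse = ", "), call. = FALSE)
  fs <- bfs_counts(g, si); ft <- bfs_counts(g, ti)
  d <- fs$dist[ti]
  through <- numeric(length(g$nodes))
  if (!is.na(d)) {
    on_path <- !is.na(fs$dist) & !is.na(ft$dist) & fs$dist + ft$dist == d
    through[on_path] <- fs$sigma[on_path] * ft$sigma[on_path]
  }
  through[c(si, ti)] <- 0
  names(through) <- g$nodes
  list(sigma = if (is.na(d)) 0 else fs$sigma[ti], through = through)
}

#' Pairwise bridge score between two life-cycle steps
#'
#' For every node v, the normalized sum over bait pairs (s in S1, t in S2)
#' of the fraction of shortest s-t paths passing through v:
#' score(v) = (1/N) * sum sigma_{s,t|v} / sigma_{s,t}, where N is the
#' number of (s, t) pairs. Pairs with no connecting path contribute 0 but
#' remain in N (set \code{exclude_unreachable} to drop them from N);
#' degenerate s = t pairs are excluded. Scores lie in [0, 1].
#'
#' @param graph Network, edge list or adjacency structure.
#' @param S1,S2 Character vectors of bait nodes of the two steps.
#' @param exclude_unreachable Drop unreachable pairs from the normalizer.
#' @return Named numeric vector of per-node scores.
#' @export
bridge_score_pairwise <- function(graph, S1, S2, exclude_unreachable = FALSE) {
  g <- as_adjacency(graph)
  if (!length(S1) || !length(S2))
    stop("empty step set", call. = FALSE)
  missing <- setdiff(c(S1, S2), g$nodes)
  if (length(missing))
    stop("node not in graph: ", paste(missing, collapse = ", "),
         call. = FALSE)
  acc <- numeric(length(g$nodes))
  n_pairs <- 0L
  cache <- list()
  getbfs <- function(v) {
    key <- as.character(v)
    if (is.null(cache[[key]])) cache[[key]] <<- bfs_counts(g, v)
    cache[[key]]
  }
  for (s in S1) for (t in S2) {
    if (s == t) next
    si <- match(s, g$nodes); ti <- match(t, g$nodes)
    fs <- getbfs(si); ft <- getbfs(ti)
    d <- fs$dist[ti]
    if (is.na(d)) {
      if (!exclude_unreachable) n_pairs <- n_pairs + 1L
      next
    }
    n_pairs <- n_pairs + 1L
    on_path <- !is.na(fs$dist) & !is.na(ft$dist) & fs$dist + ft$dist == d
    contrib <- numeric(length(acc))
    contrib[on_path] <- fs$sigma[on_path] * ft$sigma[on_path] / fs$sigma[ti]
    contrib[c(si, ti)] <- 0
    acc <- acc + contrib
  }
  if (n_pairs == 0L)
    stop("no usable (s, t) pairs between the two steps", call. = FALSE)
  stats::setNames(acc / n_pairs, g$nodes)
}

#' Bridge scores over all life-cycle step pairs
#'
#' Computes, per node, the pairwise bridge score for every pair of steps,
#' the all-steps score (the sum of all path fractions over all step pairs
#' divided by N', the total number of (s, t) pairs) and the balanced
#' all-steps score (each step pair's sum rescaled by a = 1000 / #pairs of
#' that step pair, the total divided by N'' = 1000 x #step-pairs, so that
#' each step pair carries equal weight regardless of its traffic load;
#' the factors of 1000 cancel and the balanced score equals the plain
#' mean of the pairwise scores).
#'
#' @param graph Network, edge list or adjacency structure.
#' @param steps Named character vector: life-cycle step per bait node.
#'   Nodes with step NA or "unknown" are excluded from the step sets but
#'   remain ordinary graph nodes.
#' @param exclude_unreachable Passed to the per-pair accumulation.
#' @return A \code{bridge_scores} list: \code{pairwise} (node x step-pair
#'   matrix), \code{all_steps}, \code{balanced} (named vectors),
#'   \code{n_pairs} (per step pair), \code{normalizers} (N', N'').
#' @export
bridge_score_all_steps <- function(graph, steps, exclude_unreachable = FALSE) {
  g <- as_adjacency(graph)
  steps <- steps[!is.na(steps) & steps != "unknown" &
                   names(steps) %in% g$nodes]
  step_sets <- split(names(steps), unname(steps))
  if (length(step_sets) < 2L)
    stop("need at least 2 life-cycle steps with at least 1 bait each",
         call. = FALSE)
  pairs <- utils::combn(sort(names(step_sets)), 2L)
  n_nodes <- length(g$nodes)
  n_sp <- ncol(pairs)
  pairwise <- matrix(0, n_nodes, n_sp,
                     dimnames = list(g$nodes,
                                     paste(pairs[1, ], pairs[2, ], sep = ":")))
  n_pairs <- integer(n_sp)
  for (j in seq_len(n_sp)) {
    S1 <- step_sets[[pairs[1, j]]]; S2 <- step_sets[[pairs[2, j]]]
    sc <- bridge_score_pairwise(g, S1, S2,
                                exclude_unreachable = exclude_unreachable)
    pairwise[, j] <- sc
    np <- 0L
    for (s in S1) for (t in S2) {
      if (s == t) next
      if (exclude_unreachable) {
        r <- shortest_path_counts(g, s, t)
        if (r$sigma == 0) next
      }
      np <- np + 1L
    }
    n_pairs[j] <- np
  }
  # unbalanced: sum of raw per-pair sums / N'
  n_prime <- sum(n_pairs)
  raw_sums <- sweep(pairwise, 2L, n_pairs, `*`)
  all_steps <- rowSums(raw_sums) / n_prime
  # balanced: literal a = 1000 / #pairs scaling, N'' = 1000 * #step-pairs
  a <- 1000 / n_pairs
  n_dblprime <- 1000 * n_sp
  balanced <- rowSums(sweep(raw_sums, 2L, a, `*`)) / n_dblprime
  structure(list(pairwise = pairwise, all_steps = all_steps,
                 balanced = balanced, n_pairs = n_pairs,
                 normalizers = c(N_prime = n_prime,
                                 N_doubleprime = n_dblprime)),
            class = "bridge_scores")
}

#' @export
print.bridge_scores <- function(x, ...) {
  cat(sprintf("Bridge scores: %d nodes, %d step pairs (N' = %d)\n",
              length(x$all_steps), ncol(x$pairwise),
              x$normalizers[["N_prime"]]))
  top <- utils::head(sort(x$balanced, decreasing = TRUE), 5L)
  cat("  top balanced:",
      paste(sprintf("%s %.3f", names(top), top), collapse = ", "), "\n")
  invisible(x)
}

#' Brute-force bridge-score oracle
#'
#' Verification oracle for small graphs (at most \code{max_nodes} nodes):
#' enumerates every shortest path between every bait pair by depth-first
#' search over the BFS distance structure, counts interior-node
#' occurrences literally and assembles all three score variants by direct
#' summation. Independent of the counting implementation in
#' [shortest_path_counts()] / [bridge_score_all_steps()].
#'
#' @param graph Network, edge list or adjacency structure.
#' @param steps Named character vector of step per bait node.
#' @param max_nodes Refuse larger graphs.
#' @return Same structure as [bridge_score_all_steps()].
#' @export
brute_force_bridge_oracle <- function(graph, steps, max_nodes = 12L) {
  g <- as_adjacency(graph)
  if (length(g$nodes) > max_nodes)
    stop("graph too large for the brute-force oracle", call. = FALSE)
  steps <- steps[!is.na(steps) & steps != "unknown" &
                   names(steps) %in% g$nodes]
  step_sets <- split(names(steps), unname(steps))
  if (length(step_sets) < 2L)
    stop("need at least 2 life-cycle steps", call. = FALSE)

  enumerate_paths <- function(si, ti) {
    dist_t <- bfs_counts(g, ti)$dist
    if (is.na(dist_t[si])) return(list())
    paths <- list()
    walk <- function(v, acc) {
      if (v == ti) {
        paths[[length(paths) + 1L]] <<- acc
        return(invisible())
      }
      for (w in g$adj[[v]])
        if (!is.na(dist_t[w]) && dist_t[w] == dist_t[v] - 1L)
          walk(w, c(acc, w))
    }
    walk(si, si)
    paths
  }

  nodes <- g$nodes
  pairs <- utils::combn(sort(names(step_sets)), 2L)
  n_sp <- ncol(pairs)
  pairwise <- matrix(0, length(nodes), n_sp,
                     dimnames = list(nodes,
                                     paste(pairs[1, ], pairs[2, ], sep = ":")))
  n_pairs <- integer(n_sp)
  for (j in seq_len(n_sp)) {
    S1 <- step_sets[[pairs[1, j]]]; S2 <- step_sets[[pairs[2, j]]]
    acc <- numeric(length(nodes))
    np <- 0L
    for (s in S1) for (t in S2) {
      if (s == t) next
      np <- np + 1L
      paths <- enumerate_paths(match(s, nodes), match(t, nodes))
      if (!length(paths)) next
      sigma <- length(paths)
      for (p in paths) {
        interior <- p[-c(1L, length(p))]
        for (v in interior) acc[v] <- acc[v] + 1 / sigma
      }
    }
    if (np == 0L) stop("no usable (s, t) pairs", call. = FALSE)
    pairwise[, j] <- acc / np
    n_pairs[j] <- np
  }
  n_prime <- sum(n_pairs)
  raw_sums <- sweep(pairwise, 2L, n_pairs, `*`)
  all_steps <- rowSums(raw_sums) / n_prime
  a <- 1000 / n_pairs
  n_dblprime <- 1000 * n_sp
  balanced <- rowSums(sweep(raw_sums, 2L, a, `*`)) / n_dblprime
  structure(list(pairwise = pairwise, all_steps = all_steps,
                 balanced = balanced, n_pairs = n_pairs,
                 normalizers = c(N_prime = n_prime,
                                 N_doubleprime = n_dblprime)),
            class = "bridge_scores")
}
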