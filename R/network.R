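#' Build the typed IP network from classified edges
#'
#' Deduplicates unordered bait-prey pairs. When two baits report the same
#' pair with different RNA-dependency types, all source records are kept
#' and the pair-level type is set by the precedence direct > mediated >
#' shielded > undetermined, with a conflict flag. Self edges are dropped
#' with a warning.
#'
#' @param typed_edges Data frame with columns bait, prey, type (from
#'   [classify_rna_dependency()]).
#' @param bait_steps Optional named character vector of life-cycle steps
#'   per bait, stored as node annotation.
#' @return A \code{ppi_network}: list with \code{nodes} (data.frame: node,
#'   is_bait, step) and \code{edges} (data.frame: a, b, ip_type,
#'   conflict, source_baits, sec_support).
#' @export
build_ip_network <- function(typed_edges, bait_steps = NULL) {
  e <- typed_edges
  self <- e$bait == e$prey
  if (any(self)) {
    warning(sum(self), " self edge(s) dropped", call. = FALSE)
    e <- e[!self, , drop = FALSE]
  }
  precedence <- c(direct = 1L, mediated = 2L, shielded = 3L,
                  undetermined = 4L)
  if (nrow(e)) {
    key <- pair_key(e$bait, e$prey)
    ord <- order(key, precedence[e$type])
    e2 <- e[ord, , drop = FALSE]
    k2 <- key[ord]
    first <- !duplicated(k2)
    n_types <- vapply(split(e2$type, k2), function(x) length(unique(x)),
                      integer(1))
    src <- vapply(split(e2$bait, k2),
                  function(x) paste(sort(unique(x)), collapse = ";"),
                  character(1))
    uk <- k2[first]                       # sorted unique keys
    edges <- data.frame(a = pmin(e2$bait, e2$prey)[first],
                        b = pmax(e2$bait, e2$prey)[first],
                        ip_type = e2$type[first],
                        conflict = unname(n_types[uk] > 1L),
                        source_baits = unname(src[uk]),
                        sec_support = FALSE, stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(a = character(0), b = character(0),
                        ip_type = character(0), conflict = logical(0),
                        source_baits = character(0),
                        sec_support = logical(0), stringsAsFactors = FALSE)
  }
  nodes_chr <- sort(unique(c(edges$a, edges$b)))
  baits <- unique(e$bait)
  nodes <- data.frame(node = nodes_chr, is_bait = nodes_chr %in% baits,
                      step = if (is.null(bait_steps))
                               rep(NA_character_, length(nodes_chr))
                             else unname(bait_steps[nodes_chr]),
                      stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges), class = "ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("PPI network: %d nodes, %d edges (%d with SEC support)\n",
              nrow(x$nodes), nrow(x$edges), sum(x$edges$sec_support)))
  if (nrow(x$edges) && any(!is.na(x$edges$ip_type)))
    print(table(x$edges$ip_type, useNA = "ifany"))
  invisible(x)
}

#' Merge the IP network with SEC co-elution support
#'
#' Takes the union of the IP edge set and the SEC pair set. IP edges also
#' found in SEC are collapsed into a single edge flagged with dual
#' support; SEC-only pairs (typically prey-prey interactions) enter with
#' no RNA-dependency type.
#'
#' @param ip_net A \code{ppi_network}.
#' @param sec_pairs Data frame or matrix of called co-eluting pairs
#'   (columns a, b), e.g. the called rows of [decoy_qvalues()].
#' @return A merged \code{ppi_network}.
#' @export
merge_ip_sec <- function(ip_net, sec_pairs) {
  stopifnot(inherits(ip_net, "ppi_network"))
  sec <- as.data.frame(sec_pairs, stringsAsFactors = FALSE)
  if (!nrow(sec)) return(ip_net)
  names(sec)[1:2] <- c("a", "b")
  sec_keys <- unique(pair_key(sec$a, sec$b))
  edges <- ip_net$edges
  ip_keys <- pair_key(edges$a, edges$b)
  edges$sec_support <- ip_keys %in% sec_keys

  new_keys <- setdiff(sec_keys, ip_keys)
  if (length(new_keys)) {
    ab <- do.call(rbind, strsplit(new_keys, "|", fixed = TRUE))
    edges <- rbind(edges, data.frame(
      a = ab[, 1], b = ab[, 2], ip_type = NA_character_,
      conflict = FALSE, source_baits = "", sec_support = TRUE,
      stringsAsFactors = FALSE))
  }
  nodes_chr <- sort(unique(c(edges$a, edges$b)))
  old <- ip_net$nodes[match(nodes_chr, ip_net$nodes$node), ]
  nodes <- data.frame(node = nodes_chr,
                      is_bait = !is.na(old$is_bait) & old$is_bait,
                      step = old$step, stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges), class = "ppi_network")
}

#' Annotate edges with reference support and co-localization overlap
#'
#' Adds one boolean column per reference pair list (shared membership of
#' the unordered pair) and a co-localization class per edge: \code{full}
#' when the two proteins' localization sets are identical, \code{partial}
#' when they intersect without being identical, \code{none} when disjoint,
#' \code{unknown} when either protein is unannotated.
#'
#' @param net A \code{ppi_network}.
#' @param references Named list of data frames/matrices of unordered
#'   reference pairs (columns a, b).
#' @param localization Optional data frame with columns \code{protein},
#'   \code{compartment} (one row per assignment).
#' @return The network with \code{ref_<name>} columns and (when
#'   localization is given) a \code{colocalization} column on the edges.
#' @export
annotate_reference_support <- function(net, references = list(),
                                       localization = NULL) {
  stopifnot(inherits(net, "ppi_network"))
  edges <- net$edges
  keys <- pair_key(edges$a, edges$b)
  for (nm in names(references)) {
    ref <- as.data.frame(references[[nm]], stringsAsFactors = FALSE)
    rkeys <- unique(pair_key(ref[[1]], ref[[2]]))
    edges[[paste0("ref_", nm)]] <- keys %in% rkeys
  }
  if (!is.null(localization)) {
    locs <- split(localization$compartment, localization$protein)
    edges$colocalization <- vapply(seq_len(nrow(edges)), function(i) {
      la <- locs[[edges$a[i]]]; lb <- locs[[edges$b[i]]]
      if (is.null(la) || is.null(lb)) return("unknown")
      if (setequal(la, lb)) return("full")
      if (length(intersect(la, lb))) return("partial")
      "none"
    }, character(1))
  }
  net$edges <- edges
  net
}

#' Interaction stoichiometries from unnormalized intensities
#'
#' For every IP edge with a source bait, computes the log2 prey/bait ratio
#' in the bait's IP (a proxy for the interaction stoichiometry) and the
#' log2 prey/bait ratio in the total proteome (the abundance
#' stoichiometry). Both sides are processed identically: a pseudocount of
#' 1 is added to the raw intensities, values are log2 transformed and
#' replicates averaged; the ratio is the difference of the averaged log2
#' values.
#'
#' @param net A \code{ppi_network} with IP edges.
#' @param raw An unnormalized [intensity_table()].
#' @param total_proteome Numeric matrix protein x replicate of raw total
#'   proteome intensities.
#' @return Data frame: a, b, bait, prey, stoichiometry_ip,
#'   stoichiometry_abundance (NA when bait or prey unmeasured).
#' @export
interaction_stoichiometry <- function(net, raw, total_proteome) {
  stopifnot(inherits(net, "ppi_network"), inherits(raw, "intensity_table"))
  lv <- log2(raw$values + 1)
  tp <- rowMeans(log2(total_proteome + 1), na.rm = TRUE)
  ss <- raw$samples
  edges <- net$edges[!is.na(net$edges$ip_type) | net$edges$source_baits != "", ]
  edges <- edges[edges$source_baits != "", , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(edges))) {
    for (bait in strsplit(edges$source_baits[i], ";", fixed = TRUE)[[1]]) {
      prey <- setdiff(c(edges$a[i], edges$b[i]), bait)
      if (length(prey) != 1L) next
      cols <- which(ss$role == "bait_ip" & ss$bait == bait)
      sip <- if (bait %in% rownames(lv) && prey %in% rownames(lv))
        mean(lv[prey, cols], na.rm = TRUE) - mean(lv[bait, cols], na.rm = TRUE)
      else NA_real_
      sab <- if (bait %in% names(tp) && prey %in% names(tp))
        tp[[prey]] - tp[[bait]]
      else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        a = edges$a[i], b = edges$b[i], bait = bait, prey = prey,
        stoichiometry_ip = if (is.nan(sip)) NA_real_ else sip,
        stoichiometry_abundance = if (is.nan(sab)) NA_real_ else sab,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows)
  else data.frame(a = character(0), b = character(0), bait = character(0),
                  prey = character(0), stoichiometry_ip = numeric(0),
                  stoichiometry_abundance = numeric(0))
  rownames(out) <- NULL
  out
}

#' Export a network to standard graph formats
#'
#' @param net A \code{ppi_network}.
#' @param file Output path.
#' @param format One of \code{"tsv"} (edge list with attributes),
#'   \code{"sif"} (simple interaction format, one line per edge) or
#'   \code{"graphml"}.
#' @return The file path, invisibly.
#' @export
export_network <- function(net, file, format = c("tsv", "sif", "graphml")) {
  stopifnot(inherits(net, "ppi_network"))
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(net$edges, file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else if (format == "sif") {
    rel <- ifelse(is.na(net$edges$ip_type), "sec", net$edges$ip_type)
    writeLines(paste(net$edges$a, rel, net$edges$b, sep = "\t"), file)
  } else {
    g <- as_igraph(net)
    igraph::write_graph(g, file, format = "graphml")
  }
  invisible(file)
}

#' Convert a network to an igraph object
#'
#' Nodes carry \code{is_bait} and \code{step}; edges carry their type and
#' support flags. Used for GraphML export and as a bridge to standard
#' graph tooling.
#'
#' @param net A \code{ppi_network}.
#' @return An undirected [igraph::graph].
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "ppi_network"))
  e <- net$edges
  e$ip_type[is.na(e$ip_type)] <- "sec_only"
  v <- net$nodes
  v$step[is.na(v$step)] <- ""
  igraph::graph_from_data_frame(e, directed = FALSE, vertices = v)
}

#' Read back a TSV edge-list export
#'
#' @param file Path written by [export_network()] with format "tsv".
#' @return A \code{ppi_network}.
#' @export
read_network_tsv <- function(file) {
  edges <- utils::read.delim(file, stringsAsFactors = FALSE)
  nodes_chr <- sort(unique(c(edges$a, edges$b)))
  baits <- unique(unlist(strsplit(edges$source_baits[!is.na(edges$source_baits)],
                                  ";", fixed = TRUE)))
  nodes <- data.frame(node = nodes_chr, is_bait = nodes_chr %in% baits,
                      step = NA_character_, stringsAsFactors = FALSE)
  if (!is.character(edges$source_baits))
    edges$source_baits <- as.character(edges$source_baits)
  edges$source_baits[is.na(edges$source_baits)] <- ""
  structure(list(nodes = nodes, edges = edges), class = "ppi_network")
}
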