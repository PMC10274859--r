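test_that("IP network assembly dedupes pairs with type precedence", {
  e <- data.frame(bait = c("A", "B", "C"), prey = c("B", "A", "C"),
                  type = c("direct", "mediated", "shielded"),
                  stringsAsFactors = FALSE)
  expect_warning(net <- build_ip_network(e), "self edge")
  expect_identical(nrow(net$edges), 1L)
  expect_identical(net$edges$ip_type, "direct")   # direct > mediated
  expect_true(net$edges$conflict)
  expect_identical(net$edges$source_baits, "A;B")
  # empty input gives an empty network
  empty <- build_ip_network(e[0, ])
  expect_identical(nrow(empty$edges), 0L)
  expect_identical(nrow(empty$nodes), 0L)
  # node count equals distinct endpoints
  set.seed(10)
  ed <- random_edge_df(12, 20, 11)
  ed$bait <- ed$a; ed$prey <- ed$b; ed$type <- "direct"
  net2 <- build_ip_network(ed[, c("bait", "prey", "type")])
  expect_identical(nrow(net2$nodes), length(unique(c(ed$a, ed$b))))
})

test_that("IP/SEC merge obeys the inclusion-exclusion identity", {
  e <- data.frame(bait = c("A", "B"), prey = c("B", "C"), type = "direct",
                  stringsAsFactors = FALSE)
  net <- build_ip_network(e)
  sec <- data.frame(a = c("B", "C"), b = c("C", "D"))
  merged <- merge_ip_sec(net, sec)
  expect_identical(nrow(merged$edges), 3L)        # AB, BC (dual), CD
  dual <- merged$edges$sec_support & !is.na(merged$edges$ip_type)
  expect_identical(pair_key(merged$edges$a, merged$edges$b)[dual], "B|C")
  # SEC empty leaves IP unchanged
  expect_identical(merge_ip_sec(net, sec[0, ])$edges, net$edges)
  # |A u B| = |A| + |B| - |A n B| on random sets
  for (s in 1:5) {
    ip <- random_edge_df(15, 30, s)
    ip$bait <- ip$a; ip$prey <- ip$b; ip$type <- "mediated"
    secr <- random_edge_df(15, 40, s + 100)
    n_ip <- nrow(unique(data.frame(k = pair_key(ip$a, ip$b))))
    n_sec <- length(unique(pair_key(secr$a, secr$b)))
    overlap <- length(intersect(pair_key(ip$a, ip$b),
                                pair_key(secr$a, secr$b)))
    m <- merge_ip_sec(build_ip_network(ip[, c("bait", "prey", "type")]), secr)
    expect_identical(nrow(m$edges), n_ip + n_sec - overlap)
  }
})

test_that("reference and co-localization annotation classify overlap", {
  e <- data.frame(bait = c("A", "A", "A", "A"), prey = c("B", "C", "D", "E"),
                  type = "direct", stringsAsFactors = FALSE)
  net <- build_ip_network(e)
  loc <- data.frame(
    protein = c("A", "A", "B", "C", "C", "D"),
    compartment = c("nucleus", "cytosol", "nucleus", "cytosol", "speckle",
                    "mito"),
    stringsAsFactors = FALSE)
  refs <- list(corum = data.frame(a = "A", b = "B"))
  out <- annotate_reference_support(net, refs, loc)
  keyed <- function(p) out$edges[pair_key(out$edges$a, out$edges$b) ==
                                   pair_key("A", p), ]
  expect_true(keyed("B")$ref_corum)
  expect_false(keyed("C")$ref_corum)
  expect_identical(keyed("C")$colocalization, "partial")
  expect_identical(keyed("D")$colocalization, "none")
  expect_identical(keyed("E")$colocalization, "unknown")
  # identical sets give full overlap
  loc2 <- rbind(loc, data.frame(protein = c("B"), compartment = "cytosol"))
  out2 <- annotate_reference_support(net, refs, loc2)
  e2 <- out2$edges[pair_key(out2$edges$a, out2$edges$b) == "A|B", ]
  expect_identical(e2$colocalization, "full")
})

test_that("stoichiometries are log2 prey/bait ratios and antisymmetric", {
  run <- default_run()
  net <- build_ip_network(run$hcip$edges, run$truth$bait_steps)
  total <- simulate_total_proteome(run$truth, run$cfg)
  st <- interaction_stoichiometry(net, run$raw, total)
  expect_true(all(c("stoichiometry_ip", "stoichiometry_abundance") %in%
                    names(st)))
  # recompute one record by hand
  r <- st[!is.na(st$stoichiometry_ip), ][1, ]
  ss <- run$raw$samples
  cols <- which(ss$role == "bait_ip" & ss$bait == r$bait)
  lv <- log2(run$raw$values + 1)
  want <- mean(lv[r$prey, cols], na.rm = TRUE) -
    mean(lv[r$bait, cols], na.rm = TRUE)
  expect_equal(r$stoichiometry_ip, want)
  # prey = bait intensity implies ratio 0; 8x implies 3
  expect_equal(log2(8 * 100 + 1) - log2(100 + 1), 3, tolerance = 0.02)
  # antisymmetry of the abundance ratio
  tp <- rowMeans(log2(total + 1))
  expect_equal(tp[["PREY_0002"]] - tp[["PREY_0003"]],
               -(tp[["PREY_0003"]] - tp[["PREY_0002"]]))
})

test_that("highly connected nodes have lower IP stoichiometries", {
  # the planted multi-step connector binds its partners substoichiometrically
  run <- default_run()
  te <- run$truth$edges
  net <- build_ip_network(te[, c("bait", "prey", "type")],
                          run$truth$bait_steps)
  total <- simulate_total_proteome(run$truth, run$cfg)
  st <- interaction_stoichiometry(net, run$raw, total)
  deg <- table(c(net$edges$a, net$edges$b))
  top <- names(sort(deg[grep("^PREY", names(deg))], decreasing = TRUE))[1:5]
  expect_true(run$truth$planted_bridge %in% top)
  hub <- st$stoichiometry_ip[st$prey %in% top]
  rest <- st$stoichiometry_ip[!st$prey %in% top]
  wt <- wilcox.test(hub, rest, alternative = "less")
  expect_lt(median(hub, na.rm = TRUE), median(rest, na.rm = TRUE))
  expect_lt(wt$p.value, 0.05)
})

test_that("network export round-trips across formats", {
  e <- data.frame(bait = c("A", "A", "B"), prey = c("B", "C", "C"),
                  type = c("direct", "mediated", "shielded"),
                  stringsAsFactors = FALSE)
  net <- build_ip_network(e)
  tmp <- withr::local_tempdir()
  # TSV round trip preserves nodes, edges, attributes
  f <- export_network(net, file.path(tmp, "net.tsv"), "tsv")
  back <- read_network_tsv(f)
  expect_identical(back$edges[order(back$edges$a, back$edges$b),
                              c("a", "b", "ip_type")],
                   net$edges[order(net$edges$a, net$edges$b),
                             c("a", "b", "ip_type")])
  expect_setequal(back$nodes$node, net$nodes$node)
  # SIF line count equals the edge count
  f2 <- export_network(net, file.path(tmp, "net.sif"), "sif")
  expect_length(readLines(f2), nrow(net$edges))
  # GraphML keeps attributes and topology
  f3 <- export_network(net, file.path(tmp, "net.graphml"), "graphml")
  g <- igraph::read_graph(f3, format = "graphml")
  expect_equal(igraph::gorder(g), nrow(net$nodes))
  expect_equal(igraph::gsize(g), nrow(net$edges))
  expect_true("ip_type" %in% igraph::edge_attr_names(g))
  expect_error(export_network(net, file.path(tmp, "x"), "xyz"))
})
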