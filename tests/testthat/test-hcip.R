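test_that("replicate enrichment counts use strict z > 1.645 and match a loop", {
  set.seed(3)
  v <- matrix(rnorm(40), 8, 5,
              dimnames = list(paste0("P", 1:8), paste0("m1_", 1:5)))
  v["P2", 2:3] <- c(2.0, 1.9); v["P2", 4] <- 0.1
  v["P3", 2:4] <- 1.645
  ss <- data.frame(sample_id = colnames(v), mix = 1L,
                   channel = as.character(1:5),
                   bait = c(NA, "B1", "B1", "B1", NA),
                   condition = c(NA, rep("rnase_minus", 3), "rnase_minus"),
                   replicate = c(NA, 1:3, 1),
                   role = c("spike_in", rep("bait_ip", 3), "igg"),
                   stringsAsFactors = FALSE)
  tb <- intensity_table(abs(v), ss)
  tb$values <- v
  tb$stages <- c("log2_ppm", "batch", "zscore")
  class(tb) <- c("normalized_table", class(tb))
  counts <- replicate_enrichment_flags(tb, "B1", "rnase_minus")
  expect_equal(unname(counts["P2"]), 2)     # 2.0 and 1.9 count, 0.1 not
  expect_equal(unname(counts["P3"]), 0)     # strict inequality at 1.645
  # brute-force loop oracle on the whole matrix
  for (p in rownames(v))
    expect_equal(unname(counts[p]), sum(v[p, 2:4] > 1.645))
  # fewer than 2 replicates errors
  expect_error(replicate_enrichment_flags(tb, "B9", "rnase_minus"),
               "insufficient replicates")
})

test_that("background pool combines IgG and failed-IP channels", {
  run <- default_run()
  norm <- run$norm
  igg_only <- background_pool(norm, "rnase_plus", character(0))
  with_failed <- background_pool(norm, "rnase_plus",
                                 run$hcip$qc$failed_samples)
  ss <- norm$samples
  n_igg <- sum(ss$role == "igg" & ss$condition == "rnase_plus")
  expect_identical(ncol(igg_only), n_igg)
  extra <- intersect(run$hcip$qc$failed_samples,
                     ss$sample_id[ss$condition == "rnase_plus"])
  expect_identical(ncol(with_failed), n_igg + length(extra))
  # pooled observed entries count
  expect_identical(sum(!is.na(with_failed)),
                   sum(!is.na(norm$values[, colnames(with_failed)])))
  expect_error(background_pool(norm, "no_such_condition"), "empty background")
})

test_that("enrichment test reproduces exact rank-sum probabilities", {
  # all prey above all background with within-group ties: p = 1 / C(7,3)
  st <- test_enrichment(c(10, 10, 10), c(7, 7, 7, 7))
  expect_equal(st$log2_ratio, 3)
  expect_equal(st$p_value, 1 / 35)
  # null case: identical distributions
  st0 <- test_enrichment(c(1, 2, 3), c(1, 2, 3, 4))
  expect_gte(st0$p_value, 0.5)
  expect_equal(st0$log2_ratio, 2 - 2.5)
  # all-tied degenerate input: p = 1, not an error
  expect_equal(test_enrichment(c(5, 5, 5), c(5, 5, 5, 5))$p_value, 1)
  # agreement with stats::wilcox.test exact p on tie-free data
  set.seed(4)
  for (i in 1:20) {
    x <- rnorm(4); y <- rnorm(6)
    expect_equal(test_enrichment(x, y)$p_value,
                 wilcox.test(x, y, alternative = "greater",
                             exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
})

test_that("rank-sum p-values are uniform under the null", {
  set.seed(5)
  p <- replicate(1000, {
    test_enrichment(rnorm(20), rnorm(24))$p_value
  })
  ks <- suppressWarnings(ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("HCIP calls require the full conjunction of criteria", {
  run <- default_run()
  calls <- rbind(run$hcip$calls$rnase_minus, run$hcip$calls$rnase_plus)
  expect_true(all(calls$pass == (calls$n_enriched_reps >= 2 &
                                   calls$log2_ratio > 1 &
                                   calls$p_value < calls$alpha_used),
                  na.rm = TRUE))
  expect_false(any(calls$pass[calls$log2_ratio <= 1], na.rm = TRUE))
  expect_false(any(calls$bait == calls$prey))
  # monotonicity: lowering alpha never adds a passing call
  strict <- hcip_pipeline(run$norm, alpha = 0.01)
  k_strict <- pair_key(strict$edges$bait, strict$edges$prey)
  k_default <- pair_key(run$hcip$edges$bait, run$hcip$edges$prey)
  expect_true(all(k_strict %in% k_default))
})

test_that("RNA-dependency classification follows the condition pattern", {
  qc <- data.frame(bait = rep(c("B1", "B2", "B3"), each = 2),
                   condition = rep(c("rnase_minus", "rnase_plus"), 3),
                   pass = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
                   reason = "", stringsAsFactors = FALSE)
  mkcalls <- function(bait, preys) {
    if (!length(preys)) return(NULL)
    data.frame(bait = bait, prey = preys, condition = "x",
               n_enriched_reps = 3L, log2_ratio = 2, p_value = 1e-3,
               alpha_used = 0.05, pass = TRUE, stringsAsFactors = FALSE)
  }
  minus <- rbind(mkcalls("B1", c("P1", "P2")), mkcalls("B2", "P9"))
  plus <- mkcalls("B1", c("P1", "P3"))
  out <- classify_rna_dependency(minus, plus, qc)
  get <- function(b, p) out$type[out$bait == b & out$prey == p]
  expect_identical(get("B1", "P1"), "direct")      # both conditions
  expect_identical(get("B1", "P2"), "mediated")    # minus only
  expect_identical(get("B1", "P3"), "shielded")    # plus only
  expect_identical(get("B2", "P9"), "undetermined") # bait failed one condition
  expect_false("B3" %in% out$bait)                  # failed both: dropped
  # total function: one class per pair
  expect_false(anyDuplicated(paste(out$bait, out$prey)) > 0)
})

test_that("planted interaction types are recovered on synthetic data", {
  run <- default_run()
  called <- run$hcip$edges
  truth <- run$truth
  tk <- pair_key(truth$edges$bait, truth$edges$prey)
  ck <- pair_key(called$bait, called$prey)
  expect_gte(mean(ck %in% tk), 0.9)     # precision
  expect_gte(mean(tk %in% ck), 0.9)     # recall
  for (type in c("direct", "mediated", "shielded", "undetermined")) {
    tke <- tk[truth$edges$type == type]
    cke <- ck[called$type == type]
    expect_gte(mean(tke %in% cke), 0.85)
  }
})
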