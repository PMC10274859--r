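test_that("truth generation is deterministic and respects the config", {
  cfg <- sim_config(seed = 7L)
  t1 <- make_truth(cfg)
  t2 <- make_truth(cfg)
  expect_identical(t1, t2)
  expect_length(grep("^PREY_", t1$proteins), cfg$n_preys)
  expect_length(grep("^BAIT_", t1$proteins), cfg$n_baits)
  expect_true(all(t1$edges$bait %in% t1$proteins))
  expect_true(all(t1$edges$prey %in% t1$proteins))
  expect_true(all(t1$edges$type %in%
                    c("direct", "mediated", "shielded", "undetermined")))
  # the planted bridge touches baits of at least 3 distinct steps
  bsteps <- t1$bait_steps[t1$edges$bait[t1$edges$prey == t1$planted_bridge]]
  expect_gte(length(unique(bsteps)), 3L)
  # invalid proportions rejected
  expect_error(sim_config(type_proportions = c(direct = 0.5, mediated = 0.5,
                                               shielded = 0.2,
                                               undetermined = -0.2)),
               "type_proportions")
})

test_that("edge-type frequencies follow the configured proportions", {
  # ~1000 regular edges; direct count should land in the binomial 99% CI
  cfg <- sim_config(n_baits = 12L, preys_per_bait = 91L, n_preys = 2000L,
                    seed = 3L)
  tr <- make_truth(cfg)
  reg <- tr$edges[tr$edges$planted == "regular", ]
  n <- nrow(reg)
  ci <- qbinom(c(0.005, 0.995), n, 0.20)
  expect_gte(sum(reg$type == "direct"), ci[1])
  expect_lte(sum(reg$type == "direct"), ci[2])
})

test_that("spike-in equals the channel mean when noise is zero", {
  cfg <- tiny_config(noise_sigma = 0, dropout_threshold = 0)
  tr <- make_truth(cfg)
  raw <- simulate_ip(tr, cfg)
  ss <- raw$samples
  for (m in unique(ss$mix)) {
    cols <- which(ss$mix == m)
    spike <- cols[ss$role[cols] == "spike_in"]
    rest <- setdiff(cols, spike)
    expect_equal(raw$values[, spike],
                 rowMeans(raw$values[, rest]), tolerance = 1e-12)
  }
})

test_that("direct preys are enriched by about the effect size over IgG", {
  # recompute raw log2 means over several seeds
  diffs <- vapply(1:20, function(s) {
    cfg <- tiny_config(seed = s, dropout_threshold = 0)
    tr <- make_truth(cfg)
    raw <- simulate_ip(tr, cfg)
    ss <- raw$samples
    e <- tr$edges[tr$edges$type == "direct", ][1, ]
    ip <- which(ss$role == "bait_ip" & ss$bait == e$bait)
    igg <- which(ss$role == "igg")
    mean(log2(raw$values[e$prey, ip])) - mean(log2(raw$values[e$prey, igg]))
  }, numeric(1))
  expect_equal(mean(diffs), 3.0, tolerance = 0.25)
})

test_that("IgG channels carry no planted enrichment", {
  run <- default_run()
  ss <- run$raw$samples
  igg <- which(ss$role == "igg")
  lv <- log2(run$raw$values[, igg])
  # fraction of prey values beyond the background 99.9th percentile should
  # be at chance level
  thr <- qnorm(0.999, run$cfg$background_mu,
               sqrt(run$cfg$background_sigma^2 + run$cfg$noise_sigma^2))
  frac <- mean(lv > thr, na.rm = TRUE)
  expect_lt(frac, 0.005)
})

test_that("SEC profiles put complex members on a shared apex", {
  cfg <- tiny_config(sec_noise = 0)
  tr <- make_truth(cfg)
  reps <- simulate_sec(tr, cfg)
  m <- average_sec_replicates(reps)
  expect_identical(ncol(m), 57L)          # fractions 10..66 inclusive
  expect_identical(colnames(m)[1], "10")
  expect_identical(colnames(m)[57], "66")
  cx <- tr$complexes[[2]]
  apexes <- vapply(cx, function(p) {
    prof <- m[p, ]
    as.integer(names(which.max(ifelse(is.na(prof), 0, prof))))
  }, integer(1))
  expect_true(max(apexes) - min(apexes) <= 1L)
  # apex maps back to the complex mass through the calibration inverse
  calib <- attr(reps, "calibration")
  expected_apex <- mass_to_fraction(tr$complex_mass[2], calib)
  expect_lt(abs(mean(apexes) - expected_apex), 2)
})

test_that("mass calibration is monotone and clamps out-of-range masses", {
  calib <- sec_calibration(10:66)
  expect_true(all(diff(calib$mass_kda) < 0))
  expect_warning(f <- mass_to_fraction(1e6, calib), "clamped")
  expect_equal(f, 10)
})

test_that("total proteome is positive, deterministic, 1:1 within complexes", {
  cfg <- tiny_config(seed = 5L)
  tr <- make_truth(cfg)
  t1 <- simulate_total_proteome(tr, cfg)
  t2 <- simulate_total_proteome(tr, cfg)
  expect_identical(t1, t2)
  expect_true(all(t1 > 0))
  # complex-member abundance log-ratios centred at 0 across seeds
  ratios <- vapply(1:30, function(s) {
    cfg_s <- tiny_config(seed = s)
    tr_s <- make_truth(cfg_s)
    tp <- simulate_total_proteome(tr_s, cfg_s)
    cx <- tr_s$complexes[[2]]
    lm_ <- rowMeans(log2(tp[cx, ]))
    lm_[1] - lm_[2]
  }, numeric(1))
  expect_lt(abs(mean(ratios)), 0.2)
})

test_that("binding-site sharing follows overlap_rho", {
  # rho = 1 everywhere: interacting pairs get identical sets
  cfg1 <- tiny_config(overlap_rho = c(direct = 1, mediated = 1,
                                      shielded = 1, undetermined = 1))
  tr <- make_truth(cfg1)
  sets1 <- simulate_binding_sites(tr, cfg1)
  e <- tr$edges[nrow(tr$edges), ]      # last processed edge is untouched after
  expect_equal(jaccard_index(sets1[[e$bait]], sets1[[e$prey]]), 1.0)

  # rho = 0: expected Jaccard equals the independent-inclusion baseline,
  # checked against both the first-order closed form p/(2-p) and an
  # independent Monte-Carlo oracle of Bernoulli sets
  cfg0 <- sim_config(n_baits = 8L, n_preys = 200L, preys_per_bait = 25L,
                     site_universe = 400L, seed = 31L,
                     overlap_rho = c(direct = 0, mediated = 0,
                                     shielded = 0, undetermined = 0))
  tr0 <- make_truth(cfg0)
  sets0 <- simulate_binding_sites(tr0, cfg0)
  p <- cfg0$baseline_site_rate
  n_w <- cfg0$site_universe
  set.seed(99)
  oracle <- mean(replicate(2000, {
    A <- runif(n_w) < p; B <- runif(n_w) < p
    u <- sum(A | B)
    if (u == 0) NA else sum(A & B) / u
  }), na.rm = TRUE)
  expect_equal(oracle, p / (2 - p), tolerance = 0.05)
  js <- mapply(function(a, b) jaccard_index(sets0[[a]], sets0[[b]]),
               tr0$edges$bait, tr0$edges$prey)
  expect_equal(mean(js, na.rm = TRUE), oracle, tolerance = 0.1)

  # determinism
  sets0b <- simulate_binding_sites(tr0, cfg0)
  expect_identical(lapply(sets0, `[[`, "sites"),
                   lapply(sets0b, `[[`, "sites"))
})

test_that("mean Jaccard of interacting pairs increases with overlap_rho", {
  means <- vapply(c(0.1, 0.4, 0.8), function(r) {
    cfg <- tiny_config(seed = 11L,
                       overlap_rho = c(direct = r, mediated = r,
                                       shielded = r, undetermined = r))
    tr <- make_truth(cfg)
    sets <- simulate_binding_sites(tr, cfg)
    mean(mapply(function(a, b) jaccard_index(sets[[a]], sets[[b]]),
                tr$edges$bait, tr$edges$prey), na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})
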