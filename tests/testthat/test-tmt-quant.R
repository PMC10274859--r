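make_raw <- function(values, top3 = NULL) {
  ss <- data.frame(
    sample_id = colnames(values),
    mix = 1L, channel = as.character(seq_len(ncol(values))),
    bait = NA_character_, condition = "rnase_minus",
    replicate = seq_len(ncol(values)), role = "bait_ip",
    stringsAsFactors = FALSE)
  intensity_table(values, ss, top3 = top3)
}

test_that("MS1 apportioning preserves Top3 quantities per protein and mix", {
  v <- matrix(c(0.5, 0.3, 0.2) * 10, nrow = 1,
              dimnames = list("P1", c("s1", "s2", "s3")))
  top3 <- matrix(100, 1, 1, dimnames = list("P1", "1"))
  out <- apportion_ms1(make_raw(v, top3))
  expect_equal(unname(out$values["P1", ]), c(50, 30, 20))

  # all-zero reporter row becomes missing without division errors
  v0 <- rbind(v, P2 = c(0, 0, 0))
  top3b <- matrix(100, 2, 1, dimnames = list(c("P1", "P2"), "1"))
  out0 <- apportion_ms1(make_raw(v0, top3b))
  expect_true(all(is.na(out0$values["P2", ])))

  # conservation on a random matrix, against direct summation
  set.seed(1)
  vr <- matrix(runif(60), 10, 6,
               dimnames = list(paste0("P", 1:10), paste0("s", 1:6)))
  t3 <- matrix(runif(10, 50, 150), 10, 1,
               dimnames = list(paste0("P", 1:10), "1"))
  outr <- apportion_ms1(make_raw(vr, t3))
  expect_equal(unname(rowSums(outr$values)), unname(t3[, 1]),
               tolerance = 1e-9)
})

test_that("ppm scaling and log2 transform behave at the boundaries", {
  v <- matrix(c(7, NA, NA, NA, 1, 1, 1, 1), 4, 2,
              dimnames = list(paste0("P", 1:4), c("s1", "s2")))
  out <- log2_ppm(make_raw(v))
  # single observed protein in s1: ppm 1e6
  expect_equal(out$values["P1", "s1"], log2(1e6 + 1), tolerance = 1e-9)
  # four equal proteins: each 250000 ppm
  expect_equal(unname(out$values[, "s2"]), rep(log2(250000 + 1), 4))
  # column sums of ppm equal 1e6
  back <- 2^out$values - 1
  expect_equal(unname(colSums(back, na.rm = TRUE)), c(1e6, 1e6),
               tolerance = 1)
})

test_that("batch correction matches a protein-wise loop oracle", {
  set.seed(2)
  v <- matrix(2^rnorm(40, 20, 2), 8, 5,
              dimnames = list(paste0("P", 1:8), paste0("s", 1:5)))
  v[sample(length(v), 5)] <- NA
  ss <- data.frame(sample_id = colnames(v), mix = 1L,
                   channel = as.character(1:5), bait = NA_character_,
                   condition = NA_character_, replicate = 1:5,
                   role = c("spike_in", rep("bait_ip", 2), rep("igg", 2)),
                   stringsAsFactors = FALSE)
  tb <- intensity_table(v, ss)
  out <- batch_correct(log2_ppm(tb))
  lp <- log2_ppm(intensity_table(v, ss))$values
  # brute-force loop with the spike-vs-rest rule
  for (p in rownames(v)) for (j in 1:5) {
    ref <- if (j == 1) 2:5 else setdiff(2:5, j)
    want <- lp[p, j] - mean(lp[p, ref], na.rm = TRUE)
    if (is.nan(want)) want <- NA_real_
    expect_equal(out$values[p, j], want, tolerance = 1e-12)
  }
  # example arithmetic: (4, 6, 8) -> first corrected to 4 - mean(6, 8)
  expect_equal(4 - mean(c(6, 8)), -3)
  # identical values across the mix cancel to zero
  vc <- matrix(5, 3, 5, dimnames = list(paste0("Q", 1:3), colnames(v)))
  tc <- intensity_table(vc, ss); tc$stages <- "log2_ppm"
  expect_true(all(batch_correct(tc)$values[, 2:5] == 0))
})

test_that("z-scoring standardizes columns and flags constant ones", {
  v <- matrix(c(-1, 0, 1, 2, 2, 2), 3, 2,
              dimnames = list(paste0("P", 1:3), c("s1", "s2")))
  ss <- data.frame(sample_id = c("s1", "s2"), mix = 1L,
                   channel = c("1", "2"), bait = NA_character_,
                   condition = NA_character_, replicate = 1:2,
                   role = "bait_ip", stringsAsFactors = FALSE)
  tb <- intensity_table(abs(v), ss)
  tb$values <- v
  tb$stages <- c("log2_ppm", "batch")
  expect_warning(out <- zscore_samples(tb), "constant")
  expect_equal(unname(out$values[, "s1"]), c(-1, 0, 1))
  expect_equal(unname(out$values[, "s2"]), c(0, 0, 0))
  expect_identical(attr(out, "constant_samples"), "s2")
})

test_that("the normalization chain enforces stage order and idempotence", {
  run <- default_run()
  expect_error(log2_ppm(run$norm), "already applied")
  expect_error(zscore_samples(run$raw), "requires prior stage")
  # normalized columns are standardized
  cm <- colMeans(run$norm$values, na.rm = TRUE)
  cs <- apply(run$norm$values, 2, sd, na.rm = TRUE)
  expect_true(all(abs(cm) < 1e-9))
  expect_true(all(abs(cs - 1) < 1e-9))
  expect_true(all(is.finite(run$norm$values[!is.na(run$norm$values)])))
})

test_that("failed-IP flagging applies the bait z rule and finds the planted failure", {
  run <- default_run()
  qc <- run$hcip$qc
  failed <- qc$status[!qc$status$pass, ]
  expect_true(any(failed$bait == run$truth$undetermined_bait &
                    failed$condition == run$truth$undetermined_fail_condition))
  # the planted failing bait passes the other condition
  other <- qc$status[qc$status$bait == run$truth$undetermined_bait &
                       qc$status$condition != run$truth$undetermined_fail_condition, ]
  expect_true(all(other$pass))
  # every retained bait has >= 2 replicates in >= 1 passing condition
  expect_true(all(run$truth$baits %in% qc$retained_baits))
})
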