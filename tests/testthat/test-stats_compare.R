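test_that("normality_scan calibrates on normal and flags exponential samples", {
  set.seed(25)
  hits_norm <- 0L; hits_exp <- 0L
  for (i in 1:200) {
    mn <- matrix(rnorm(21 * 3), 21, 3)
    tb <- table_from_matrix(mn)
    if (all(normality_scan(tb, "f", 1)$p > 0.05)) hits_norm <- hits_norm + 1L
    me <- matrix(rexp(21 * 3), 21, 3)
    te <- table_from_matrix(me)
    if (any(normality_scan(te, "f", 1)$p < 0.05)) hits_exp <- hits_exp + 1L
  }
  # normal data should rarely be flagged; exponential nearly always
  expect_gte(hits_norm / 200, 0.75)   # (1 - 0.05)^3 ~ 0.857 expected
  expect_gte(hits_exp / 200, 0.8)
  # per-phase power: a single exponential phase is flagged > 80% of the time
  set.seed(26)
  one_phase <- mean(replicate(200, {
    tb <- table_from_matrix(cbind(rexp(21), rnorm(21), rnorm(21)))
    normality_scan(tb, "f", 1)$p[1] < 0.05
  }))
  expect_gte(one_phase, 0.8)
  # constant sample -> degenerate, NA-marked with warning
  tbc <- table_from_matrix(cbind(rep(1, 21), rnorm(21), rnorm(21)))
  expect_warning(ns <- normality_scan(tbc, "f", 1), "constant")
  expect_true(is.na(ns$p[1]))
})

test_that("friedman_across_phases: degenerate, powered and guarded cases", {
  # all phases identical per subject -> stat 0, p 1
  v <- rnorm(21)
  tb <- table_from_matrix(cbind(v, v, v))
  fr <- friedman_across_phases(tb, "f", 1)
  expect_equal(fr$stat, 0)
  expect_equal(fr$p, 1)
  # one phase shifted by 10 SDs -> p < 0.001
  set.seed(27)
  tb10 <- table_from_matrix(cbind(rnorm(21), rnorm(21) + 10, rnorm(21)))
  expect_lt(friedman_across_phases(tb10, "f", 1)$p, 0.001)
  # fewer than 5 complete blocks -> refusal
  tb2 <- table_from_matrix(matrix(rnorm(12), 4, 3))
  expect_error(friedman_across_phases(tb2, "f", 1), "complete blocks")
  # incomplete subjects are dropped and counted
  m <- matrix(rnorm(30), 10, 3); m[1, 2] <- NA
  fr2 <- friedman_across_phases(table_from_matrix(m), "f", 1)
  expect_equal(fr2$n_blocks, 9)
  expect_equal(fr2$n_dropped, 1)
})

test_that("Friedman statistic is invariant to within-subject monotone transforms", {
  set.seed(28)
  m <- matrix(rlnorm(21 * 3), 21, 3)
  f1 <- friedman_across_phases(table_from_matrix(m), "f", 1)
  f2 <- friedman_across_phases(table_from_matrix(log(m)), "f", 1)
  f3 <- friedman_across_phases(table_from_matrix(m^3), "f", 1)
  expect_equal(f1$stat, f2$stat)
  expect_equal(f1$stat, f3$stat)
})

test_that("posthoc_pairwise: gatekeeping, constructed difference, null case", {
  set.seed(29)
  # contract error without a significant omnibus
  v <- rnorm(21)
  fr_null <- friedman_across_phases(table_from_matrix(cbind(v, v, v)), "f", 1)
  expect_error(posthoc_pairwise(fr_null), "significant omnibus")
  # phases A = B, C shifted: A-C and B-C significant, A-B not
  a <- rnorm(21)
  m <- cbind(a, a + rnorm(21, 0, 0.1), a + 5)
  fr <- friedman_across_phases(table_from_matrix(m), "f", 1)
  pw <- posthoc_pairwise(fr)
  sig_ab <- pw$significant[pw$phase_a == "IAPS" & pw$phase_b == "IADS"]
  sig_ac <- pw$significant[pw$phase_a == "IAPS" & pw$phase_b == "IAPS+IADS"]
  sig_bc <- pw$significant[pw$phase_a == "IADS" & pw$phase_b == "IAPS+IADS"]
  expect_false(sig_ab)
  expect_true(sig_ac)
  expect_true(sig_bc)
  expect_true(all(pw$corrected_p >= 0 & pw$corrected_p <= 1))
})

test_that("compare_feature gatekeeps the pairwise stage", {
  set.seed(30)
  m_null <- matrix(rnorm(21 * 3), 21, 3)
  # force a null-ish table; pairwise only present when omnibus significant
  cmp <- compare_feature(table_from_matrix(m_null), "f", 1)
  if (cmp$friedman_p >= 0.05) expect_null(cmp$pairwise)
  m_eff <- cbind(rnorm(21), rnorm(21) + 8, rnorm(21))
  cmp2 <- compare_feature(table_from_matrix(m_eff), "f", 1)
  expect_false(is.null(cmp2$pairwise))
  expect_equal(cmp2$dimension, "arousal")
  cmp3 <- compare_feature(table_from_matrix(m_eff, segment = "low"), "f", 1,
                          segment = "low")
  expect_equal(cmp3$dimension, "valence")
})

test_that("feature tables round-trip and reject duplicate keys", {
  tb <- table_from_matrix(matrix(rnorm(15), 5, 3))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_feature_table(tb, path)
  tb2 <- read_feature_table(path)
  expect_equal(tb2$value, tb$value)
  expect_error(feature_table(c(1, 1), "IAPS", 1, "whole", "f", c(1, 2)),
               "duplicate")
})
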