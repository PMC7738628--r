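mk_profiles <- function(genes, directions, age, kinetics = "lasting",
                        biphasic = FALSE, amp = NULL) {
  n <- length(genes)
  data.frame(gene_id = genes, age = age, p3 = TRUE, p6 = FALSE, p12 = FALSE,
             p24 = TRUE, fc3 = 2, fc6 = NA, fc12 = NA, fc24 = 2,
             kinetics = rep_len(kinetics, n),
             biphasic = rep_len(biphasic, n),
             dominant_direction = rep_len(directions, n),
             max_abs_log2fc = if (is.null(amp)) rep(1, n) else amp,
             stringsAsFactors = FALSE)
}

test_that("cross-age partition is exact set algebra", {
  p5 <- mk_profiles(c("A", "B"), c("induced", "repressed"), "P5")
  p10 <- mk_profiles(c("A", "C"), c("induced", "induced"), "P10")
  out <- intersect_ages(p5, p10)
  part <- out$partition
  expect_equal(part$status[part$gene_id == "A"], "common")
  expect_equal(part$status[part$gene_id == "B"], "p5_specific")
  expect_equal(part$status[part$gene_id == "C"], "p10_specific")

  # opposite dominant directions are kept out of the common core
  p10b <- mk_profiles(c("A", "C"), c("repressed", "induced"), "P10")
  out2 <- intersect_ages(p5, p10b)
  expect_equal(out2$partition$status[out2$partition$gene_id == "A"],
               "opposite")
  expect_equal(out2$summary$n_common, 0)

  # disjoint lists share nothing
  out3 <- intersect_ages(mk_profiles("X", "induced", "P5"),
                         mk_profiles("Y", "induced", "P10"))
  expect_equal(out3$summary$n_common, 0)
  expect_equal(out3$summary$n_union, 2)
})

test_that("partition statuses are complete and disjoint", {
  set.seed(13)
  for (i in 1:10) {
    g5 <- sample(sprintf("G%03d", 1:60), 30)
    g10 <- sample(sprintf("G%03d", 1:60), 35)
    p5 <- mk_profiles(g5, sample(c("induced", "repressed"), 30, TRUE), "P5")
    p10 <- mk_profiles(g10, sample(c("induced", "repressed"), 35, TRUE),
                       "P10")
    out <- intersect_ages(p5, p10)
    s <- out$summary
    expect_equal(s$n_common + s$n_opposite + s$n_p5_specific +
                   s$n_p10_specific, s$n_union)
    expect_equal(s$n_union, length(union(g5, g10)))
    expect_equal(anyDuplicated(out$partition$gene_id), 0)
  }
})

test_that("isochronous subset needs identical kinetics and no biphasy", {
  genes <- c("A", "B", "C", "D")
  p5 <- mk_profiles(genes, "induced", "P5",
                    kinetics = c("lasting", "early", "late", "lasting"),
                    biphasic = c(FALSE, FALSE, FALSE, TRUE))
  p10 <- mk_profiles(genes, "induced", "P10",
                     kinetics = c("lasting", "late", "late", "lasting"))
  part <- intersect_ages(p5, p10)$partition
  iso <- isochronous_subset(part, p5, p10)
  expect_equal(iso, c("A", "C"))   # B: early vs late; D: biphasic
})

test_that("time-course overlap counts match a brute-force tally", {
  calls5 <- data.frame(
    gene_id = c("A", "A", "B", "C"), probe_id = paste0("p", 1:4),
    age = "P5", time_h = c(3L, 6L, 3L, 12L), fc = c(2, 2.2, -3, 2),
    p_adj = NA_real_, rule = "A_replicated_2x",
    direction = c("induced", "induced", "repressed", "induced"),
    splice_conflict = FALSE, stringsAsFactors = FALSE)
  calls10 <- data.frame(
    gene_id = c("A", "B"), probe_id = paste0("q", 1:2),
    age = "P10", time_h = c(3L, 3L), fc = c(2.5, 2.1),
    p_adj = NA_real_, rule = "A_replicated_2x",
    direction = c("induced", "induced"),
    splice_conflict = FALSE, stringsAsFactors = FALSE)
  out <- overlap_timecourse(calls5, calls10)
  at3_ind <- out$per_time[out$per_time$time_h == 3 &
                            out$per_time$direction == "induced", ]
  expect_equal(at3_ind$both, 1)        # A at both ages
  expect_equal(at3_ind$p10_only, 1)    # B induced at P10 only at 3 h
  at3_rep <- out$per_time[out$per_time$time_h == 3 &
                            out$per_time$direction == "repressed", ]
  expect_equal(at3_rep$p5_only, 1)     # B repressed at P5
  expect_equal(out$persistence$n_persisting[
    out$persistence$age == "P5" & out$persistence$from_h == 3], 1)  # A
  # empty call lists give an all-zero matrix
  empty <- calls5[0, ]
  zero <- overlap_timecourse(empty, empty)
  expect_true(all(zero$per_time[c("p5_only", "p10_only", "both")] == 0))
  expect_true(all(zero$persistence$n_persisting == 0))
})

test_that("amplitude correlation reproduces the closed-form Pearson r", {
  x <- c(1.2, 2.0, 2.8, 3.1, 4.5)
  y <- c(1.0, 2.2, 2.5, 3.6, 4.1)
  out <- amplitude_correlation(x, y)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(out$r, r_hand, tolerance = 1e-12)
  expect_equal(out$r2, r_hand^2, tolerance = 1e-12)
  expect_equal(amplitude_correlation(x, x)$r2, 1)
  set.seed(99)
  a <- rnorm(2000); b <- rnorm(2000)
  expect_lt(amplitude_correlation(a, b)$r2, 0.01)
  expect_error(amplitude_correlation(c(1, 1, 1), c(1, 2, 3)),
               "zero variance")
})

test_that("Mann-Whitney U matches exhaustive rank enumeration", {
  expect_error(compare_amplitudes(numeric(0), 1:3), "empty")
  ident <- compare_amplitudes(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ident$U, 9 / 2)     # n^2 / 2 under exchangeability
  expect_equal(ident$p, 1)
  sep <- compare_amplitudes(c(1, 2, 3), c(10, 11, 12))
  expect_equal(sep$U, 0)
  expect_equal(compare_amplitudes(c(10, 11, 12), c(1, 2, 3))$U, 9)
  set.seed(7)
  for (i in 1:25) {
    a <- round(runif(sample(2:8, 1), 0, 10), 1)
    b <- round(runif(sample(2:8, 1), 0, 10), 1)
    got <- compare_amplitudes(a, b)
    expect_equal(got$U, oracle_mann_whitney_u(a, b))
    # exchanging samples reflects U about n_a * n_b / 2
    expect_equal(compare_amplitudes(b, a)$U,
                 length(a) * length(b) - got$U)
  }
})

test_that("medians and interquartiles accompany the amplitude comparison", {
  out <- compare_amplitudes(c(1, 2, 3, 4, 100), c(2, 4, 6, 8))
  expect_equal(out$median_a, 3)
  expect_equal(out$median_b, 5)
  expect_equal(out$iqr_a, unname(quantile(c(1, 2, 3, 4, 100), c(.25, .75))))
})
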