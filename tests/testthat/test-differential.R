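# one probe, one contrast, chosen replicate ratios
ratio_table <- function(ratios, cy3 = 500, probe = "P1", gene = "G1") {
  data.frame(probe_id = probe, gene_id = gene, age = "P5", time_h = 6L,
             condition = "HI", replicate = seq_along(ratios),
             cy3 = cy3, cy5 = cy3 * ratios, stringsAsFactors = FALSE)
}

test_that("BH adjustment matches the hand step-up computation", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  set.seed(42)
  for (i in 1:20) {
    p <- runif(sample(3:40, 1))
    expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
    # re-adjusting never lowers a value and keeps the significance ordering
    once <- bh_adjust(p)
    twice <- bh_adjust(once)
    expect_true(all(twice >= once - 1e-12))
    expect_equal(order(twice, p), order(once, p))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("median centering shifts log-ratios and preserves differences", {
  tab <- ratio_table(c(2, 2.5, 1.8))
  tab2 <- ratio_table(c(1.1, 0.9, 1.4), probe = "P2", gene = "G2")
  tab2$replicate <- 1:3
  both <- rbind(tab, tab2)
  centered <- center_ratios(both)
  for (rep_i in 1:3) {
    sub <- centered[centered$replicate == rep_i, ]
    expect_equal(median(log2(sub$cy5 / sub$cy3)), 0, tolerance = 1e-12)
  }
  # within-array differences in log-ratio are untouched
  lr0 <- log2(both$cy5 / both$cy3)
  lr1 <- log2(centered$cy5 / centered$cy3)
  for (rep_i in 1:3) {
    i <- which(both$replicate == rep_i)
    expect_equal(diff(lr0[i]), diff(lr1[i]), tolerance = 1e-12)
  }
  # an already-centered array is unchanged
  again <- center_ratios(centered)
  expect_equal(again$cy5, centered$cy5, tolerance = 1e-12)
})

test_that("rule A fires on 2-of-3 replicated twofold changes", {
  calls <- call_hi_effects(ratio_table(c(2.6, 2.4, 1.1)), call_thresholds(),
                           "P5", 6)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$rule, "A_replicated_2x")
  expect_equal(calls$direction, "induced")
  expect_equal(calls$fc, prod(c(2.6, 2.4, 1.1))^(1 / 3), tolerance = 1e-12)
  expect_true(is.na(calls$p_adj))

  # mixed-direction 2-of-3 must not fire
  mixed <- call_hi_effects(ratio_table(c(2.6, 1 / 2.6, 1.0)),
                           call_thresholds(), "P5", 6)
  expect_equal(nrow(mixed), 0)

  # repression side: same rule on inverted ratios
  rep_calls <- call_hi_effects(ratio_table(1 / c(2.6, 2.4, 1.1)),
                               call_thresholds(), "P5", 6)
  expect_equal(rep_calls$direction, "repressed")
  expect_equal(rep_calls$fc, -prod(c(2.6, 2.4, 1.1))^(1 / 3),
               tolerance = 1e-12)
})

test_that("probes under the floor in both channels are excluded", {
  low <- ratio_table(c(3, 3, 3), cy3 = 25)   # cy5 = 75: both means < 100
  expect_equal(nrow(call_hi_effects(low, call_thresholds(), "P5", 6)), 0)
  # one channel above the floor is enough to stay in
  high5 <- ratio_table(c(3, 3, 3), cy3 = 40)  # cy5 = 120
  expect_equal(nrow(call_hi_effects(high5, call_thresholds(), "P5", 6)), 1)
  # flat ratios never call
  flat <- ratio_table(c(1, 1, 1))
  expect_equal(nrow(call_hi_effects(flat, call_thresholds(), "P5", 6)), 0)
})

test_that("HI calling equals the brute-force oracle over random tables", {
  thr <- call_thresholds()
  for (seed in 301:360) {
    tab <- random_probe_table(seed)
    got <- call_hi_effects(tab, thr, "P5", 6)
    want <- oracle_call_hi(tab, thr, "P5", 6)
    expect_identical(got$probe_id, want$probe_id)
    expect_equal(got$fc, want$fc, tolerance = 1e-12)
    expect_identical(got$rule, want$rule)
    expect_identical(got$direction, want$direction)
  }
})

test_that("tightening any threshold never increases the number of calls", {
  tab <- do.call(rbind, lapply(1:4, function(s) {
    t <- random_probe_table(s, n_probes = 25)
    t$probe_id <- paste0(t$probe_id, "_", s)
    t$gene_id <- paste0(t$gene_id, "_", s)
    t
  }))
  base <- nrow(call_hi_effects(tab, call_thresholds(), "P5", 6))
  tighter <- list(call_thresholds(fc_rule_a = 2.5),
                  call_thresholds(fc_rule_b = 1.8),
                  call_thresholds(alpha_b = 0.01),
                  call_thresholds(min_replicates_a = 3),
                  call_thresholds(signal_floor = 300))
  for (thr in tighter) {
    expect_lte(nrow(call_hi_effects(tab, thr, "P5", 6)), base)
  }
})

test_that("probe-to-gene collapse keeps the strongest probe per gene", {
  calls <- data.frame(
    gene_id = c("G1", "G1", "G2", "G3", "G3"),
    probe_id = c("p1", "p2", "p3", "p4", "p5"),
    age = "P5", time_h = 6L,
    fc = c(2.1, 3.5, 2.0, 2.5, -2.5),
    p_adj = NA_real_, rule = "A_replicated_2x",
    direction = c("induced", "induced", "induced", "induced", "repressed"),
    stringsAsFactors = FALSE)
  out <- collapse_probes(calls)
  expect_equal(out$fc[out$gene_id == "G1"], 3.5)
  expect_equal(out$fc[out$gene_id == "G2"], 2.0)   # singleton passes through
  g3 <- out[out$gene_id == "G3", ]
  expect_equal(nrow(g3), 2)                        # opposite signs both kept
  expect_true(all(g3$splice_conflict))
  expect_false(any(out$splice_conflict[out$gene_id != "G3"]))
})

test_that("collapse drops unannotated probes with a message", {
  calls <- data.frame(gene_id = c("G1", ""), probe_id = c("p1", "p2"),
                      age = "P5", time_h = 3L, fc = c(2, 3),
                      p_adj = NA_real_, rule = "A_replicated_2x",
                      direction = "induced", stringsAsFactors = FALSE)
  expect_message(out <- collapse_probes(calls), "unannotated")
  expect_equal(out$gene_id, "G1")
})

dev_table <- function(x1, x2, stages = c("P5", "P10"), probe = "P1",
                      gene = "G1") {
  rbind(
    data.frame(probe_id = probe, gene_id = gene, age = stages[1],
               time_h = NA_integer_, condition = "naive",
               replicate = seq_along(x1), cy3 = x1, cy5 = NA_real_,
               stringsAsFactors = FALSE),
    data.frame(probe_id = probe, gene_id = gene, age = stages[2],
               time_h = NA_integer_, condition = "naive",
               replicate = seq_along(x2), cy3 = x2, cy5 = NA_real_,
               stringsAsFactors = FALSE))
}

test_that("developmental calling detects a planted fourfold increase", {
  set.seed(31)
  x1 <- 400 * rlnorm(8, 0, 0.05)
  x2 <- 1600 * rlnorm(8, 0, 0.05)
  out <- call_dev_changes(dev_table(x1, x2), call_thresholds(), "P5-P10")
  expect_equal(nrow(out), 1)
  expect_gt(out$fc, 2)
  expect_lt(out$p_adj, 0.001)
  # direction flips with the stages
  down <- call_dev_changes(dev_table(x2, x1), call_thresholds(), "P5-P10")
  expect_lt(down$fc, -2)
})

test_that("developmental calling applies background and null guards", {
  # identical groups: no call
  x <- rep(500, 8)
  expect_equal(nrow(call_dev_changes(dev_table(x, x), call_thresholds(),
                                     "P5-P10")), 0)
  # both stage means < 200: excluded before testing
  set.seed(5)
  lo1 <- 40 * rlnorm(8, 0, 0.05); lo2 <- 160 * rlnorm(8, 0, 0.05)
  expect_equal(nrow(call_dev_changes(dev_table(lo1, lo2), call_thresholds(),
                                     "P5-P10")), 0)
  expect_error(call_dev_changes(dev_table(x, x), call_thresholds(), "P4-P6"),
               "interval")
})

test_that("developmental calling equals the brute-force oracle", {
  thr <- call_thresholds()
  for (seed in 1:30) {
    set.seed(seed + 1000)
    n <- 20
    rows <- list()
    for (i in seq_len(n)) {
      basal <- 10^runif(1, 1.5, 3.5)
      fold <- if (runif(1) < 0.4) 2^runif(1, -2.5, 2.5) else 1
      rows[[i]] <- dev_table(basal * rlnorm(8, 0, 0.1),
                             basal * fold * rlnorm(8, 0, 0.1),
                             probe = sprintf("P%03d", i),
                             gene = sprintf("G%03d", i))
    }
    tab <- do.call(rbind, rows)
    got <- call_dev_changes(tab, thr, "P5-P10")
    want <- oracle_call_dev(tab, thr, "P5-P10")
    expect_identical(got$probe_id, want$probe_id)
    expect_equal(got$fc, want$fc, tolerance = 1e-12)
  }
})
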