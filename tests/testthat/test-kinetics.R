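test_that("all 16 detection patterns map to their kinetic class", {
  # hand-enumerated from the class definitions: lasting = present at both
  # endpoints; early = at 3 h, gone by 24 h; late = at 24 h, absent at 3 h;
  # transient = only 6/12 h
  expected <- c("0000" = "none",
                "1000" = "early",   "0100" = "transient",
                "0010" = "transient", "0001" = "late",
                "1100" = "early",   "1010" = "early",
                "1001" = "lasting", "0110" = "transient",
                "0101" = "late",    "0011" = "late",
                "1110" = "early",   "1101" = "lasting",
                "1011" = "lasting", "0111" = "late",
                "1111" = "lasting")
  for (code in names(expected)) {
    pattern <- as.integer(strsplit(code, "")[[1]]) == 1
    expect_equal(classify_kinetics(pattern), expected[[code]],
                 label = paste("pattern", code))
  }
  # the four classes partition the 15 non-empty patterns
  classes <- vapply(1:15, function(i) {
    classify_kinetics(as.logical(bitwAnd(i, c(8, 4, 2, 1)) > 0))
  }, character(1))
  expect_setequal(unique(classes), c("early", "transient", "late", "lasting"))
})

gene_calls <- function(times, fcs, gene = "G1", age = "P5") {
  data.frame(gene_id = gene, probe_id = paste0("p", seq_along(times)),
             age = age, time_h = as.integer(times), fc = fcs,
             p_adj = NA_real_, rule = "A_replicated_2x",
             direction = ifelse(fcs > 0, "induced", "repressed"),
             splice_conflict = FALSE, stringsAsFactors = FALSE)
}

test_that("detect_pattern reads calls into patterns and dominant direction", {
  d <- detect_pattern(gene_calls(c(3, 6), c(2.2, 2.0)))
  expect_equal(d$pattern, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(d$dominant_direction, "induced")

  d <- detect_pattern(gene_calls(12, 1.8))
  expect_equal(d$pattern, c(FALSE, FALSE, TRUE, FALSE))

  d <- detect_pattern(gene_calls(c(3, 24), c(2.1, -3.0)))
  expect_equal(d$pattern, c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(d$dominant_direction, "repressed")
  expect_equal(d$fc, c(2.1, NA, NA, -3.0))
})

test_that("biphasic flag requires significant calls of both signs", {
  expect_true(flag_biphasic(c(2, NA, NA, -2.8)))
  expect_false(flag_biphasic(c(2, NA, NA, 3)))
  expect_false(flag_biphasic(c(NA, 2.5, NA, NA)))
})

test_that("R-Index follows its formula and is linear in each fold change", {
  expect_equal(compute_r_index(2.0, 1000), 6.0)
  expect_equal(compute_r_index(c(1.8, -2.5), 10^2.5), -1.75)
  expect_equal(compute_r_index(c(2, 2, 2, 2), 10), 8.0)
  expect_equal(compute_r_index(c(NA, 2, NA, 3), 100), 10.0)
  # linear in each significant FC; monotone in basal
  expect_equal(compute_r_index(c(3, 4), 500),
               compute_r_index(3, 500) + compute_r_index(4, 500))
  expect_lt(compute_r_index(2, 200), compute_r_index(2, 2000))
  expect_error(compute_r_index(numeric(0), 100), "at least one")
  expect_error(compute_r_index(2, 0.5), "basal")
})

test_that("decile ranking matches a hand-sorted oracle", {
  set.seed(17)
  n <- 20
  records <- data.frame(
    gene_id = sprintf("G%02d", 1:n), age = "P5",
    r_index = sample(c(-1, 1), n, TRUE) * runif(n, 1, 50),
    basal_cy3 = 500, direction = "induced", decile = NA_integer_,
    stringsAsFactors = FALSE)
  ranked <- rank_deciles(records)
  ord <- order(-abs(records$r_index), records$gene_id)
  oracle <- integer(n)
  oracle[ord] <- ceiling(10 * seq_len(n) / n)
  expect_equal(ranked$decile, oracle)
  # top |R-Index| lands in decile 1; 100 distinct values spread 10 per decile
  expect_equal(ranked$decile[which.max(abs(ranked$r_index))], 1L)
  big <- data.frame(gene_id = sprintf("G%03d", 1:100), age = "P10",
                    r_index = seq(101, 200), basal_cy3 = 500,
                    direction = "repressed", decile = NA_integer_,
                    stringsAsFactors = FALSE)
  expect_equal(unname(table(rank_deciles(big)$decile)),
               array(rep(10L, 10)))
  expect_warning(rank_deciles(records[1:5, ]), "deciles are empty")
})

test_that("strata are ranked independently by age and direction", {
  records <- expand.grid(age = c("P5", "P10"),
                         direction = c("induced", "repressed"),
                         i = 1:12, stringsAsFactors = FALSE)
  records$gene_id <- sprintf("G%03d", seq_len(nrow(records)))
  records$r_index <- records$i * ifelse(records$direction == "induced", 1, -1)
  records$basal_cy3 <- 500
  records$decile <- NA_integer_
  ranked <- rank_deciles(records[, c("gene_id", "age", "r_index", "basal_cy3",
                                     "direction", "decile")])
  for (a in c("P5", "P10")) {
    for (d in c("induced", "repressed")) {
      sub <- ranked[records$age == a & records$direction == d, ]
      expect_equal(sub$decile[order(-abs(sub$r_index))],
                   ceiling(10 * (1:12) / 12))
    }
  }
})

test_that("decile uniformity test reduces to the Pearson formula", {
  flat <- decile_uniformity_test(rep(5, 10))
  expect_equal(flat$chi2, 0)
  expect_equal(flat$p, 1)
  spike <- decile_uniformity_test(c(50, rep(0, 9)))
  expect_equal(spike$chi2, 450)   # (50-5)^2/5 + 9 * 25/5
  expect_equal(spike$df, 9)
  # invariant under permutation of the deciles
  counts <- c(9, 1, 4, 6, 2, 8, 3, 7, 5, 5)
  expect_equal(decile_uniformity_test(counts)$chi2,
               decile_uniformity_test(rev(counts))$chi2)
  expect_error(decile_uniformity_test(rep(0, 10)), "empty")
})

test_that("kinetics profiles combine pattern, class, biphasic and amplitude", {
  calls <- rbind(gene_calls(c(3, 24), c(2.0, -2.8), gene = "G1"),
                 gene_calls(c(6, 12), c(1.8, 2.2), gene = "G2"),
                 gene_calls(c(3, 6, 12, 24), c(2, 2.5, 2.2, 2.1),
                            gene = "G3"))
  prof <- kinetics_profiles(calls, "P5")
  expect_equal(prof$kinetics, c("lasting", "transient", "lasting"))
  expect_equal(prof$biphasic, c(TRUE, FALSE, FALSE))
  expect_equal(prof$dominant_direction, c("repressed", "induced", "induced"))
  expect_equal(prof$max_abs_log2fc[2], log2(2.2))
})
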