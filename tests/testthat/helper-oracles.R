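# Independent brute-force oracles: literal, loop-based re-statements of the
# filtering rules and statistics, kept deliberately separate from the
# package's vectorised implementations.

oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    rank_i <- which(ord == i)
    # step-up: min over all ranks >= rank_i of p * m / rank
    candidates <- vapply(rank_i:m, function(j) p[ord[j]] * m / j, numeric(1))
    adj[i] <- min(1, min(candidates))
  }
  adj
}

# literal application of the two-color calling rules to one contrast
oracle_call_hi <- function(table, thr, age, time_h) {
  rows <- table[!is.na(table$time_h) & table$age == age &
                  table$time_h == time_h, ]
  probes <- sort(unique(rows$probe_id))
  stats_list <- list()
  for (pb in probes) {
    r <- rows[rows$probe_id == pb, ]
    r <- r[order(r$replicate), ]
    if (nrow(r) < 2) next
    if (mean(r$cy3) < thr$signal_floor && mean(r$cy5) < thr$signal_floor) next
    ratio <- r$cy5 / r$cy3
    lr <- log2(ratio)
    n_up <- sum(ratio > thr$fc_rule_a)
    n_down <- sum(ratio < 1 / thr$fc_rule_a)
    gm <- exp(mean(log(ratio)))
    rule_a <- (n_up >= thr$min_replicates_a && mean(lr) > 0) ||
      (n_down >= thr$min_replicates_a && mean(lr) < 0)
    if (stats::sd(lr) == 0) {
      p <- if (mean(lr) != 0) 0 else 1
    } else {
      p <- stats::t.test(lr, mu = 0)$p.value
    }
    stats_list[[pb]] <- list(probe = pb, gene = r$gene_id[1], gm = gm,
                             mean_lr = mean(lr), rule_a = rule_a, p = p)
  }
  if (length(stats_list) == 0) {
    return(data.frame(probe_id = character(0), fc = numeric(0),
                      rule = character(0), direction = character(0)))
  }
  p_adj <- oracle_bh(vapply(stats_list, `[[`, numeric(1), "p"))
  out <- list()
  for (i in seq_along(stats_list)) {
    s <- stats_list[[i]]
    rule_b <- abs(s$mean_lr) > log2(thr$fc_rule_b) && p_adj[i] < thr$alpha_b
    fc <- if (s$gm >= 1) s$gm else -1 / s$gm
    if ((s$rule_a || rule_b) && abs(fc) >= thr$fc_rule_b) {
      out[[length(out) + 1]] <- data.frame(
        probe_id = s$probe, fc = fc,
        rule = if (s$rule_a) "A_replicated_2x" else "B_bh_t",
        direction = if (fc > 0) "induced" else "repressed",
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    return(data.frame(probe_id = character(0), fc = numeric(0),
                      rule = character(0), direction = character(0)))
  }
  res <- do.call(rbind, out)
  res[order(res$probe_id), , drop = FALSE]
}

# literal application of the one-color developmental rules to one interval
oracle_call_dev <- function(table, thr, interval) {
  stages <- strsplit(interval, "-")[[1]]
  rows <- table[is.na(table$time_h) & table$age %in% stages, ]
  probes <- sort(unique(rows$probe_id))
  stats_list <- list()
  for (pb in probes) {
    x1 <- rows$cy3[rows$probe_id == pb & rows$age == stages[1]]
    x2 <- rows$cy3[rows$probe_id == pb & rows$age == stages[2]]
    if (mean(x1) < thr$dev_background_mult * thr$signal_floor &&
        mean(x2) < thr$dev_background_mult * thr$signal_floor) next
    if (any(c(x1, x2) <= 0)) next
    l1 <- log2(x1); l2 <- log2(x2)
    if (stats::sd(l1) == 0 && stats::sd(l2) == 0) {
      p <- if (mean(l1) != mean(l2)) 0 else 1
    } else {
      p <- stats::t.test(l2, l1, var.equal = TRUE)$p.value
    }
    ratio <- mean(x2) / mean(x1)
    fc <- if (ratio >= 1) ratio else -1 / ratio
    stats_list[[pb]] <- list(probe = pb, fc = fc, p = p)
  }
  if (length(stats_list) == 0) {
    return(data.frame(probe_id = character(0), fc = numeric(0)))
  }
  p_adj <- oracle_bh(vapply(stats_list, `[[`, numeric(1), "p"))
  keep <- vapply(seq_along(stats_list), function(i) {
    abs(stats_list[[i]]$fc) >= thr$dev_fc && p_adj[i] < thr$dev_alpha
  }, logical(1))
  res <- data.frame(
    probe_id = vapply(stats_list, `[[`, character(1), "probe"),
    fc = vapply(stats_list, `[[`, numeric(1), "fc"),
    stringsAsFactors = FALSE)[keep, , drop = FALSE]
  rownames(res) <- NULL
  res[order(res$probe_id), , drop = FALSE]
}

# exhaustive Mann-Whitney U: count pairs (a_i, b_j) with a_i > b_j (+0.5 ties)
oracle_mann_whitney_u <- function(a, b) {
  u <- 0
  for (x in a) for (y in b) {
    u <- u + (x > y) + 0.5 * (x == y)
  }
  u
}

# upper hypergeometric tail via binomial coefficients only
oracle_hyper_tail <- function(k, K, N, n) {
  total <- 0
  for (x in k:min(K, n)) {
    total <- total + choose(K, x) * choose(N - K, n - x) / choose(N, n)
  }
  total
}

# two-sided Fisher exact p for a 2x2 table by enumerating all tables with
# the same margins and summing probabilities <= that of the observed table
oracle_fisher_2x2 <- function(m) {
  a <- m[1, 1]; b <- m[1, 2]; c <- m[2, 1]; d <- m[2, 2]
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  prob <- function(x) {
    choose(c1, x) * choose(n - c1, r1 - x) / choose(n, r1)
  }
  p_obs <- prob(a)
  total <- 0
  for (x in max(0, r1 - (n - c1)):min(r1, c1)) {
    px <- prob(x)
    if (px <= p_obs * (1 + 1e-07)) total <- total + px
  }
  total
}

# random small two-color table for oracle-equivalence fuzzing: a mix of
# unregulated, strongly regulated and sub-floor probes
random_probe_table <- function(seed, n_probes = 30, age = "P5",
                               time_h = 6L) {
  set.seed(seed)
  basal <- 10^stats::runif(n_probes, 1.2, 3.8)
  ratio <- rep(1, n_probes)
  reg <- stats::runif(n_probes) < 0.4
  ratio[reg] <- 2^(stats::runif(sum(reg), -2.5, 2.5))
  rows <- list()
  for (i in seq_len(n_probes)) {
    for (rep_i in 1:3) {
      noise3 <- stats::rlnorm(1, 0, 0.2)
      noise5 <- stats::rlnorm(1, 0, 0.2)
      rows[[length(rows) + 1]] <- data.frame(
        probe_id = sprintf("P%03d", i), gene_id = sprintf("G%03d", i),
        age = age, time_h = time_h, condition = "HI", replicate = rep_i,
        cy3 = basal[i] * noise3, cy5 = basal[i] * ratio[i] * noise5,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
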