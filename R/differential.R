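#' Calling thresholds
#'
#' The defaults are the study's filtering rules. Two-color HI effects are
#' recorded on probes with a replicate fold change above 2 in at least 2 of 3
#' replicates in the same direction (rule A), or a mean fold change above 1.5
#' with a one-sample t-test of the replicate log-ratios against zero
#' surviving Benjamini-Hochberg correction at 0.05 (rule B). Probes with both
#' channel means under the 100-unit floor are excluded before either rule.
#' Developmental changes require a twofold change between stage means, a
#' BH-corrected unpaired t-test below 0.001, and at least twofold background
#' (200 units) in one stage.
#'
#' @param fc_rule_a replicate fold-change cut of rule A.
#' @param min_replicates_a replicates (of 3) that must clear `fc_rule_a`.
#' @param fc_rule_b mean fold-change cut of rule B.
#' @param alpha_b BH-adjusted significance level of rule B.
#' @param signal_floor detection floor in signal units.
#' @param dev_fc developmental fold-change cut.
#' @param dev_alpha developmental BH-adjusted significance level.
#' @param dev_background_mult background multiple of the floor required of at
#'   least one stage mean.
#' @return list of class `call_thresholds`.
#' @export
call_thresholds <- function(fc_rule_a = 2.0, min_replicates_a = 2L,
                            fc_rule_b = 1.5, alpha_b = 0.05,
                            signal_floor = 100, dev_fc = 2.0,
                            dev_alpha = 0.001, dev_background_mult = 2.0) {
  t <- list(fc_rule_a = fc_rule_a, min_replicates_a = as.integer(min_replicates_a),
            fc_rule_b = fc_rule_b, alpha_b = alpha_b,
            signal_floor = signal_floor, dev_fc = dev_fc,
            dev_alpha = dev_alpha, dev_background_mult = dev_background_mult)
  if (any(unlist(t) <= 0)) stop("all thresholds must be positive")
  if (alpha_b >= 1 || dev_alpha >= 1) stop("alpha values must be in (0, 1)")
  class(t) <- "call_thresholds"
  t
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p vector of p-values in [0, 1].
#' @return adjusted p-values, capped at 1.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop("p-values must be finite and in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Median-center per-array log-ratios
#'
#' Optional normalisation hook: shifts every array (one age x time x
#' replicate) so its median log2(Cy5/Cy3) is zero. Off by default in the
#' pipeline because input tables are assumed Lowess-normalised upstream.
#' Within-array ratio differences are preserved exactly.
#'
#' @param table two-color probe table.
#' @return probe table with centered `cy5`.
#' @export
center_ratios <- function(table) {
  two_color <- !is.na(table$time_h)
  if (!any(two_color)) stop("no two-color rows to center")
  key <- paste(table$age, table$time_h, table$replicate)[two_color]
  cy3 <- table$cy3[two_color]
  cy5 <- table$cy5[two_color]
  if (any(tapply(cy3 + cy5, key, function(x) all(x == 0)))) {
    stop("array with all-zero signals")
  }
  logr <- log2(cy5 / cy3)
  med <- tapply(logr, key, stats::median)
  table$cy5[two_color] <- cy5 / 2^med[key]
  table
}

# reshape one contrast into probe x replicate channel matrices
contrast_matrices <- function(table, age, time_h) {
  rows <- table[!is.na(table$time_h) & table$age == age &
                  table$time_h == time_h & table$condition == "HI", ]
  if (nrow(rows) == 0) return(NULL)
  probes <- sort(unique(rows$probe_id))
  reps <- sort(unique(rows$replicate))
  idx <- cbind(match(rows$probe_id, probes), match(rows$replicate, reps))
  cy3 <- cy5 <- matrix(NA_real_, length(probes), length(reps),
                       dimnames = list(probes, reps))
  cy3[idx] <- rows$cy3
  cy5[idx] <- rows$cy5
  gene <- rows$gene_id[match(probes, rows$probe_id)]
  list(probes = probes, gene = gene, cy3 = cy3, cy5 = cy5)
}

empty_calls <- function() {
  data.frame(gene_id = character(0), probe_id = character(0),
             age = character(0), time_h = integer(0), fc = numeric(0),
             p_adj = numeric(0), rule = character(0),
             direction = character(0), stringsAsFactors = FALSE)
}

#' Call HI-regulated probes for one age x time contrast
#'
#' Applies the detection floor, then the two calling rules (see
#' [call_thresholds()]). The reported fold change is the signed linear fold
#' of the geometric-mean replicate ratio; repressions are negative (-x means
#' a ratio of 1/x). The BH family of rule B is all floor-passing probes of
#' the contrast. `p_adj` is reported for rule-B calls only.
#'
#' @param table two-color probe table.
#' @param thresholds [call_thresholds()].
#' @param age `"P5"` or `"P10"`.
#' @param time_h one of 3, 6, 12, 24.
#' @return probe-level calls: `gene_id`, `probe_id`, `age`, `time_h`, `fc`,
#'   `p_adj`, `rule`, `direction`.
#' @export
call_hi_effects <- function(table, thresholds = call_thresholds(), age,
                            time_h) {
  m <- contrast_matrices(table, age, time_h)
  if (is.null(m)) return(empty_calls())
  n_rep <- rowSums(!is.na(m$cy3) & !is.na(m$cy5))
  usable <- n_rep >= 2 & rowSums(m$cy3 == 0, na.rm = TRUE) == 0 &
    rowSums(m$cy5 == 0, na.rm = TRUE) == 0
  if (any(!usable)) {
    warning(sum(!usable), " probe(s) skipped (fewer than 2 replicates or ",
            "zero signal) in ", age, " ", time_h, " h")
  }
  keep_floor <- !(rowMeans(m$cy3, na.rm = TRUE) < thresholds$signal_floor &
                    rowMeans(m$cy5, na.rm = TRUE) < thresholds$signal_floor)
  idx <- which(usable & keep_floor)
  if (length(idx) == 0) return(empty_calls())

  logr <- log2(m$cy5[idx, , drop = FALSE] / m$cy3[idx, , drop = FALSE])
  n <- rowSums(!is.na(logr))
  mean_lr <- rowMeans(logr, na.rm = TRUE)
  sd_lr <- apply(logr, 1, stats::sd, na.rm = TRUE)

  # rule A: per-replicate linear fold > fc_rule_a, same direction, >= 2 of 3,
  # agreeing with the sign of the mean log-ratio
  cut_a <- log2(thresholds$fc_rule_a)
  n_up <- rowSums(logr > cut_a, na.rm = TRUE)
  n_down <- rowSums(logr < -cut_a, na.rm = TRUE)
  rule_a <- (n_up >= thresholds$min_replicates_a & mean_lr > 0) |
    (n_down >= thresholds$min_replicates_a & mean_lr < 0)

  # rule B: one-sample t of replicate log-ratios against zero, BH over all
  # floor-passing probes; zero replicate variance with nonzero mean is taken
  # as p = 0 (the replicates agree exactly)
  tstat <- mean_lr / (sd_lr / sqrt(n))
  p <- 2 * stats::pt(-abs(tstat), df = n - 1)
  p[sd_lr == 0] <- ifelse(mean_lr[sd_lr == 0] != 0, 0, 1)
  p_adj <- bh_adjust(p)
  rule_b <- abs(mean_lr) > log2(thresholds$fc_rule_b) &
    p_adj < thresholds$alpha_b

  fc <- ifelse(mean_lr >= 0, 2^mean_lr, -2^(-mean_lr))
  called <- (rule_a | rule_b) & abs(fc) >= thresholds$fc_rule_b
  if (!any(called)) return(empty_calls())
  sel <- which(called)
  out <- data.frame(
    gene_id = m$gene[idx][sel], probe_id = m$probes[idx][sel],
    age = age, time_h = as.integer(time_h), fc = fc[sel],
    p_adj = ifelse(rule_a[sel], NA_real_, p_adj[sel]),
    rule = ifelse(rule_a[sel], "A_replicated_2x", "B_bh_t"),
    direction = ifelse(fc[sel] > 0, "induced", "repressed"),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$probe_id), , drop = FALSE]
}

#' Call HI effects on every age x time contrast present in a table
#'
#' @inheritParams call_hi_effects
#' @return probe-level calls for all contrasts, row-bound.
#' @export
call_hi_all <- function(table, thresholds = call_thresholds()) {
  out <- list()
  for (age in HI_AGES) {
    for (time_h in HI_TIMES) {
      out[[paste(age, time_h)]] <- call_hi_effects(table, thresholds, age,
                                                   time_h)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Collapse probe-level calls to gene level
#'
#' For each gene x age x time point, the probe with the largest absolute
#' log2 fold change represents the gene. When probes of one gene are called
#' in opposite directions at the same contrast, the strongest probe of each
#' direction is retained and both records are flagged `splice_conflict`
#' (distinct probes reporting opposite signals suggest alternative
#' transcripts). Probes without a gene id are dropped here, with a message.
#'
#' @param calls probe-level calls from [call_hi_effects()] / [call_hi_all()].
#' @return gene-level calls with an extra logical `splice_conflict` column.
#' @export
collapse_probes <- function(calls) {
  unann <- !nzchar(calls$gene_id) | is.na(calls$gene_id)
  if (any(unann)) {
    message(sum(unann), " call(s) on unannotated probes dropped at gene collapse")
    calls <- calls[!unann, , drop = FALSE]
  }
  if (nrow(calls) == 0) {
    out <- empty_calls()
    out$splice_conflict <- logical(0)
    return(out)
  }
  key <- paste(calls$gene_id, calls$age, calls$time_h, sep = "\r")
  pieces <- lapply(split(calls, key), function(g) {
    g <- g[order(-abs(log2(abs(g$fc))), g$probe_id), , drop = FALSE]
    conflict <- length(unique(g$direction)) > 1
    keep <- g[!duplicated(if (conflict) g$direction else rep(1, nrow(g))), ,
              drop = FALSE]
    keep$splice_conflict <- conflict
    keep
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out[order(out$age, out$time_h, out$gene_id, out$direction), , drop = FALSE]
}

#' Call developmental changes between two stages
#'
#' One-color analysis between the endpoint stages of `interval`: probes with
#' at least `dev_background_mult` x floor mean signal in one stage are
#' tested; a change requires an absolute fold of stage means of at least
#' `dev_fc` and a BH-adjusted equal-variance unpaired t-test on log2 signals
#' below `dev_alpha`. The sign of `fc` encodes later vs earlier stage.
#'
#' @param table one-color probe table (cy3 only).
#' @param thresholds [call_thresholds()].
#' @param interval one of `"P2-P5"`, `"P5-P10"`, `"P10-P15"`, `"P2-P15"`.
#' @return data.frame: `gene_id`, `probe_id`, `interval`, `fc`, `p_adj`.
#' @export
call_dev_changes <- function(table, thresholds = call_thresholds(),
                             interval) {
  if (!interval %in% DEV_INTERVALS) {
    stop("interval must be one of ", paste(DEV_INTERVALS, collapse = ", "))
  }
  stages <- strsplit(interval, "-", fixed = TRUE)[[1]]
  rows <- table[is.na(table$time_h) & table$age %in% stages, ]
  if (nrow(rows) == 0) stop("no one-color rows for interval ", interval)
  probes <- sort(unique(rows$probe_id))
  sig <- function(stage) {
    r <- rows[rows$age == stage, ]
    reps <- sort(unique(r$replicate))
    m <- matrix(NA_real_, length(probes), length(reps),
                dimnames = list(probes, reps))
    m[cbind(match(r$probe_id, probes), match(r$replicate, reps))] <- r$cy3
    m
  }
  m1 <- sig(stages[1])
  m2 <- sig(stages[2])
  gene <- rows$gene_id[match(probes, rows$probe_id)]

  mean1 <- rowMeans(m1, na.rm = TRUE)
  mean2 <- rowMeans(m2, na.rm = TRUE)
  floor_x <- thresholds$dev_background_mult * thresholds$signal_floor
  keep <- which((mean1 >= floor_x | mean2 >= floor_x) &
                  mean1 > 0 & mean2 > 0)
  if (length(keep) == 0) {
    return(data.frame(gene_id = character(0), probe_id = character(0),
                      interval = character(0), fc = numeric(0),
                      p_adj = numeric(0), stringsAsFactors = FALSE))
  }

  l1 <- log2(m1[keep, , drop = FALSE])
  l2 <- log2(m2[keep, , drop = FALSE])
  n1 <- rowSums(!is.na(l1)); n2 <- rowSums(!is.na(l2))
  v1 <- apply(l1, 1, stats::var, na.rm = TRUE)
  v2 <- apply(l2, 1, stats::var, na.rm = TRUE)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  diff <- rowMeans(l2, na.rm = TRUE) - rowMeans(l1, na.rm = TRUE)
  tstat <- diff / se
  p <- 2 * stats::pt(-abs(tstat), df = n1 + n2 - 2)
  p[se == 0] <- ifelse(diff[se == 0] != 0, 0, 1)
  p_adj <- bh_adjust(p)

  ratio <- mean2[keep] / mean1[keep]
  fc <- ifelse(ratio >= 1, ratio, -1 / ratio)
  called <- abs(fc) >= thresholds$dev_fc & p_adj < thresholds$dev_alpha
  out <- data.frame(gene_id = gene[keep][called],
                    probe_id = probes[keep][called],
                    interval = rep(interval, sum(called)), fc = fc[called],
                    p_adj = p_adj[called], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$probe_id), , drop = FALSE]
}

#' Collapse probe-level developmental changes to gene level
#'
#' Per gene x interval, the probe with the largest absolute log2 fold
#' represents the gene; unannotated probes are dropped.
#'
#' @param changes output of [call_dev_changes()] (one or several intervals
#'   row-bound).
#' @return gene-level changes.
#' @export
collapse_dev_changes <- function(changes) {
  changes <- changes[nzchar(changes$gene_id) & !is.na(changes$gene_id), ,
                     drop = FALSE]
  if (nrow(changes) == 0) return(changes)
  key <- paste(changes$gene_id, changes$interval, sep = "\r")
  ord <- order(key, -abs(log2(abs(changes$fc))), changes$probe_id)
  changes <- changes[ord, , drop = FALSE]
  out <- changes[!duplicated(key[ord]), , drop = FALSE]
  rownames(out) <- NULL
  out[order(out$interval, out$gene_id), , drop = FALSE]
}
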