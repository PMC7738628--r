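#' Partition regulated genes across the two ages
#'
#' Genes regulated at both ages with the same dominant direction form the
#' common (core) response; genes regulated at both ages in opposite dominant
#' directions are kept apart; the rest are age-specific. Percentages are
#' reported against both per-age list sizes and the union, since both
#' denominators are informative.
#'
#' @param profiles_p5,profiles_p10 [kinetics_profiles()] outputs for the
#'   two ages.
#' @return list: `partition` (gene_id, status in {common, p5_specific,
#'   p10_specific, opposite}, dir_p5, dir_p10) and `summary` (counts and
#'   percentages).
#' @export
intersect_ages <- function(profiles_p5, profiles_p10) {
  genes <- sort(union(profiles_p5$gene_id, profiles_p10$gene_id))
  dir5 <- profiles_p5$dominant_direction[match(genes, profiles_p5$gene_id)]
  dir10 <- profiles_p10$dominant_direction[match(genes, profiles_p10$gene_id)]
  status <- ifelse(is.na(dir10), "p5_specific",
            ifelse(is.na(dir5), "p10_specific",
            ifelse(dir5 == dir10, "common", "opposite")))
  partition <- data.frame(gene_id = genes, status = status,
                          dir_p5 = dir5, dir_p10 = dir10,
                          stringsAsFactors = FALSE)
  n5 <- nrow(profiles_p5); n10 <- nrow(profiles_p10)
  n_common <- sum(status == "common")
  summary <- list(
    n_p5 = n5, n_p10 = n10, n_union = length(genes),
    n_common = n_common, n_opposite = sum(status == "opposite"),
    n_p5_specific = sum(status == "p5_specific"),
    n_p10_specific = sum(status == "p10_specific"),
    common_pct_p5 = if (n5 > 0) 100 * n_common / n5 else NA_real_,
    common_pct_p10 = if (n10 > 0) 100 * n_common / n10 else NA_real_,
    common_pct_union = if (length(genes) > 0)
      100 * n_common / length(genes) else NA_real_)
  list(partition = partition, summary = summary)
}

#' Genes regulated isochronously at both ages
#'
#' Common-direction genes whose kinetic class is identical at the two ages;
#' genes biphasic at either age are excluded.
#'
#' @param partition partition from [intersect_ages()].
#' @param profiles_p5,profiles_p10 kinetics profiles of the two ages.
#' @return character vector of gene ids.
#' @export
isochronous_subset <- function(partition, profiles_p5, profiles_p10) {
  common <- partition$gene_id[partition$status == "common"]
  k5 <- profiles_p5$kinetics[match(common, profiles_p5$gene_id)]
  k10 <- profiles_p10$kinetics[match(common, profiles_p10$gene_id)]
  b5 <- profiles_p5$biphasic[match(common, profiles_p5$gene_id)]
  b10 <- profiles_p10$biphasic[match(common, profiles_p10$gene_id)]
  sort(common[k5 == k10 & !b5 & !b10])
}

#' Per-time-point overlap and persistence of calls across ages
#'
#' @param calls_p5,calls_p10 gene-level calls of the two ages.
#' @return list: `per_time` (per time point, counts of induced/repressed
#'   genes called at P5 only, P10 only, or both) and `persistence` (per age
#'   and consecutive time-point pair, genes called at both time points).
#' @export
overlap_timecourse <- function(calls_p5, calls_p10) {
  genes_at <- function(calls, time_h, dir) {
    unique(calls$gene_id[calls$time_h == time_h & calls$direction == dir])
  }
  per_time <- do.call(rbind, lapply(HI_TIMES, function(tt) {
    do.call(rbind, lapply(c("induced", "repressed"), function(dir) {
      g5 <- genes_at(calls_p5, tt, dir)
      g10 <- genes_at(calls_p10, tt, dir)
      data.frame(time_h = tt, direction = dir,
                 p5_only = length(setdiff(g5, g10)),
                 p10_only = length(setdiff(g10, g5)),
                 both = length(intersect(g5, g10)),
                 stringsAsFactors = FALSE)
    }))
  }))
  persist_one <- function(calls, age) {
    do.call(rbind, lapply(seq_len(length(HI_TIMES) - 1), function(i) {
      g1 <- unique(calls$gene_id[calls$time_h == HI_TIMES[i]])
      g2 <- unique(calls$gene_id[calls$time_h == HI_TIMES[i + 1]])
      data.frame(age = age, from_h = HI_TIMES[i], to_h = HI_TIMES[i + 1],
                 n_persisting = length(intersect(g1, g2)),
                 stringsAsFactors = FALSE)
    }))
  }
  persistence <- rbind(persist_one(calls_p5, "P5"),
                       persist_one(calls_p10, "P10"))
  rownames(per_time) <- rownames(persistence) <- NULL
  list(per_time = per_time, persistence = persistence)
}

#' Cross-age correlation of response amplitudes (or R-Indexes)
#'
#' Pearson correlation between the per-age values of the common-direction
#' genes, reported as r-squared with its two-sided p-value.
#'
#' @param x,y numeric vectors of per-age values of the same genes (e.g. max
#'   absolute log2 fold change, or R-Index), aligned by gene.
#' @return list: `r`, `r2`, `p`, `n`.
#' @export
amplitude_correlation <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in one of the amplitude vectors")
  }
  ht <- stats::cor.test(x, y, method = "pearson")
  r <- unname(ht$estimate)
  list(r = r, r2 = r^2, p = ht$p.value, n = length(x))
}

#' Compare two amplitude samples (Mann-Whitney)
#'
#' Two-sided Mann-Whitney U with the normal approximation and tie
#' correction; medians and interquartile ranges of both samples are
#' reported alongside.
#'
#' @param a,b numeric samples (absolute fold changes).
#' @return list: `median_a`, `iqr_a`, `median_b`, `iqr_b`, `U` (statistic of
#'   sample `a`), `p`.
#' @export
compare_amplitudes <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) stop("empty amplitude sample")
  ht <- suppressWarnings(
    stats::wilcox.test(a, b, exact = FALSE, correct = FALSE))
  list(median_a = stats::median(a),
       iqr_a = unname(stats::quantile(a, c(0.25, 0.75))),
       median_b = stats::median(b),
       iqr_b = unname(stats::quantile(b, c(0.25, 0.75))),
       U = unname(ht$statistic), p = ht$p.value)
}
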