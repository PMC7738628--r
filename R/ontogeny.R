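#' Flanking developmental intervals of each insult age
#' @keywords internal
flanking_intervals <- function(age) {
  switch(age,
         P5 = c(previous = "P2-P5", subsequent = "P5-P10"),
         P10 = c(previous = "P5-P10", subsequent = "P10-P15"),
         stop("age must be P5 or P10"))
}

#' Classify HI effects against spontaneous developmental regulation
#'
#' A gene's HI response at one age is coincident when the gene also shows a
#' significant developmental change in either flanking interval (previous
#' or subsequent). Coincident genes are `ortho` when the HI dominant
#' direction matches the developmental direction of the reference interval
#' and `antagonistic` otherwise. When both flanking intervals are
#' significant with conflicting signs, the subsequent interval is the
#' reference (the insult is read against the expression program it
#' anticipates); otherwise the single significant interval is.
#'
#' @param profiles [kinetics_profiles()] of the age's HI-regulated genes.
#' @param dev_changes gene-level developmental changes
#'   ([collapse_dev_changes()]) covering the flanking intervals.
#' @param age `"P5"` or `"P10"`.
#' @return data.frame: `gene_id`, `age`, `coincident`, `relation` (`ortho`,
#'   `antagonistic`, or NA when not coincident), `reference_interval`.
#' @export
coincidence_classify <- function(profiles, dev_changes, age) {
  flank <- flanking_intervals(age)
  dir_in <- function(interval) {
    d <- dev_changes[dev_changes$interval == interval, ]
    sign(d$fc[match(profiles$gene_id, d$gene_id)])
  }
  s_prev <- dir_in(flank[["previous"]])
  s_subs <- dir_in(flank[["subsequent"]])
  coincident <- !is.na(s_prev) | !is.na(s_subs)
  ref <- ifelse(!is.na(s_subs), flank[["subsequent"]],
                ifelse(!is.na(s_prev), flank[["previous"]], NA_character_))
  dev_sign <- ifelse(!is.na(s_subs), s_subs, s_prev)
  hi_sign <- ifelse(profiles$dominant_direction == "induced", 1, -1)
  relation <- ifelse(!coincident, NA_character_,
                     ifelse(hi_sign == dev_sign, "ortho", "antagonistic"))
  data.frame(gene_id = profiles$gene_id, age = rep(age, nrow(profiles)),
             coincident = coincident,
             relation = relation, reference_interval = ref,
             stringsAsFactors = FALSE)
}

#' Detect transient developmental waves
#'
#' Classifies each gene's trajectory over two consecutive developmental
#' intervals: `up_down` (significant increase then significant decrease),
#' `down_up` (the reverse), `monotone` (same sign in both intervals, or a
#' change in exactly one), `none` (no change in either).
#'
#' @param dev_changes gene-level developmental changes.
#' @param intervals character 2-vector of consecutive intervals, default
#'   `c("P5-P10", "P10-P15")`.
#' @return data.frame: `gene_id`, `wave`.
#' @export
transient_wave_detect <- function(dev_changes,
                                  intervals = c("P5-P10", "P10-P15")) {
  stopifnot(length(intervals) == 2)
  genes <- sort(unique(
    dev_changes$gene_id[dev_changes$interval %in% intervals]))
  s <- vapply(intervals, function(iv) {
    d <- dev_changes[dev_changes$interval == iv, ]
    sign(d$fc[match(genes, d$gene_id)])
  }, numeric(length(genes)))
  if (length(genes) == 1) s <- matrix(s, nrow = 1)
  wave <- rep("none", length(genes))
  both <- !is.na(s[, 1]) & !is.na(s[, 2])
  one <- xor(is.na(s[, 1]), is.na(s[, 2]))
  wave[one | (both & s[, 1] == s[, 2])] <- "monotone"
  wave[both & s[, 1] > 0 & s[, 2] < 0] <- "up_down"
  wave[both & s[, 1] < 0 & s[, 2] > 0] <- "down_up"
  data.frame(gene_id = genes, wave = wave, stringsAsFactors = FALSE)
}

#' Contingency test (Pearson chi-square or Fisher exact)
#'
#' Pearson chi-square is computed without continuity correction; the Fisher
#' test is two-sided and restricted to 2 x 2 tables.
#'
#' @param counts matrix of non-negative integer counts.
#' @param method `"chi2"` or `"fisher"`.
#' @return for `"chi2"`: list `statistic`, `df`, `p`; for `"fisher"`: list
#'   `odds_ratio`, `p`.
#' @export
contingency_test <- function(counts, method = c("chi2", "fisher")) {
  method <- match.arg(method)
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("zero marginal row or column")
  }
  if (method == "chi2") {
    ht <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
    list(statistic = unname(ht$statistic), df = unname(ht$parameter),
         p = ht$p.value)
  } else {
    if (!all(dim(counts) == c(2, 2))) stop("Fisher test requires a 2x2 table")
    ht <- stats::fisher.test(counts)
    list(odds_ratio = unname(ht$estimate), p = ht$p.value)
  }
}
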