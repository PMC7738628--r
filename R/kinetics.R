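#' Classify a detection pattern into a kinetic class
#'
#' The four classes partition all non-empty detection patterns over the
#' 3/6/12/24 h time points:
#' \itemize{
#'   \item \strong{lasting}: detected at both 3 h and 24 h (gaps allowed);
#'   \item \strong{early}: detected at 3 h but back below threshold by 24 h;
#'   \item \strong{late}: detected at 24 h but not at 3 h;
#'   \item \strong{transient}: detected only at 6 and/or 12 h;
#'   \item \strong{none}: no detection at any time point.
#' }
#'
#' @param pattern logical 4-vector for detection at 3, 6, 12, 24 h.
#' @return one of `"early"`, `"transient"`, `"late"`, `"lasting"`, `"none"`.
#' @export
classify_kinetics <- function(pattern) {
  stopifnot(length(pattern) == 4, is.logical(pattern) || all(pattern %in% 0:1))
  pattern <- as.logical(pattern)
  if (!any(pattern)) return("none")
  if (pattern[1] && pattern[4]) return("lasting")
  if (pattern[1]) return("early")
  if (pattern[4]) return("late")
  "transient"
}

#' Detection pattern and per-time fold changes of one gene at one age
#'
#' @param gene_calls gene-level calls ([collapse_probes()]) of a single gene
#'   at a single age; opposite-direction `splice_conflict` duplicates at one
#'   time point are resolved to the strongest record.
#' @return list: `pattern` (logical 4-vector over 3/6/12/24 h), `fc` (signed
#'   linear fold per time point, NA where not called), `dominant_direction`
#'   (direction of the largest-amplitude call).
#' @export
detect_pattern <- function(gene_calls) {
  stopifnot(nrow(gene_calls) >= 1,
            length(unique(gene_calls$gene_id)) == 1,
            length(unique(gene_calls$age)) == 1)
  fc <- rep(NA_real_, 4)
  for (i in seq_along(HI_TIMES)) {
    at <- gene_calls[gene_calls$time_h == HI_TIMES[i], , drop = FALSE]
    if (nrow(at) > 0) fc[i] <- at$fc[which.max(abs(at$fc))]
  }
  pattern <- !is.na(fc)
  dominant <- if (fc[which.max(abs(fc))] > 0) "induced" else "repressed"
  list(pattern = pattern, fc = fc, dominant_direction = dominant)
}

#' Flag biphasic responses
#'
#' @param fc per-time signed fold changes (NA where not significant).
#' @return TRUE iff significant calls of both signs exist across the time
#'   course.
#' @export
flag_biphasic <- function(fc) {
  s <- sign(fc[!is.na(fc)])
  any(s > 0) && any(s < 0)
}

#' Kinetics profiles for all genes called at one age
#'
#' @param gene_calls gene-level calls for one age.
#' @param age the age, echoed into the output.
#' @return data.frame: `gene_id`, `age`, detection flags `p3`/`p6`/`p12`/
#'   `p24`, fold changes `fc3`..`fc24`, `kinetics`, `biphasic`,
#'   `dominant_direction`, `max_abs_log2fc`.
#' @export
kinetics_profiles <- function(gene_calls, age) {
  gene_calls <- gene_calls[gene_calls$age == age, , drop = FALSE]
  if (nrow(gene_calls) == 0) {
    return(data.frame(gene_id = character(0), age = character(0),
                      p3 = logical(0), p6 = logical(0), p12 = logical(0),
                      p24 = logical(0), fc3 = numeric(0), fc6 = numeric(0),
                      fc12 = numeric(0), fc24 = numeric(0),
                      kinetics = character(0), biphasic = logical(0),
                      dominant_direction = character(0),
                      max_abs_log2fc = numeric(0), stringsAsFactors = FALSE))
  }
  pieces <- lapply(split(gene_calls, gene_calls$gene_id), function(g) {
    d <- detect_pattern(g)
    data.frame(gene_id = g$gene_id[1], age = age,
               p3 = d$pattern[1], p6 = d$pattern[2], p12 = d$pattern[3],
               p24 = d$pattern[4],
               fc3 = d$fc[1], fc6 = d$fc[2], fc12 = d$fc[3], fc24 = d$fc[4],
               kinetics = classify_kinetics(d$pattern),
               biphasic = flag_biphasic(d$fc),
               dominant_direction = d$dominant_direction,
               max_abs_log2fc = max(abs(log2(abs(d$fc))), na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out[order(out$gene_id), , drop = FALSE]
}

#' Regulation index of one gene at one age
#'
#' R-Index = (sum of the signed linear fold changes at the time points with
#' a significant call) x log10(basal Cy3). It integrates amplitude,
#' duration and basal expression into one signed score; biphasic genes
#' partially cancel because repressions enter as negative folds.
#'
#' @param fc signed linear fold changes of the significant calls.
#' @param basal_cy3 basal naive Cy3 signal (> 1).
#' @return the signed R-Index.
#' @export
compute_r_index <- function(fc, basal_cy3) {
  fc <- fc[!is.na(fc)]
  if (length(fc) == 0) stop("R-Index needs at least one significant call")
  if (!is.finite(basal_cy3) || basal_cy3 <= 1) {
    stop("basal_cy3 must exceed 1 (log10 weight must be positive)")
  }
  sum(fc) * log10(basal_cy3)
}

# geometric mean of naive Cy3 over the age's four time-matched contrasts,
# per gene (all probes and replicates of the gene pooled)
basal_cy3_by_gene <- function(table, age) {
  rows <- table[!is.na(table$time_h) & table$age == age &
                  nzchar(table$gene_id) & table$cy3 > 0, ]
  gm <- tapply(log10(rows$cy3), rows$gene_id, mean)
  10^gm
}

#' R-Index records for all genes called at one age
#'
#' @param profiles [kinetics_profiles()] output for the age.
#' @param table the two-color probe table (source of the basal Cy3 signal:
#'   geometric mean of naive Cy3 over the age's four time-matched contrasts).
#' @return data.frame: `gene_id`, `age`, `r_index`, `basal_cy3`,
#'   `direction` (dominant), `decile` (filled by [rank_deciles()]).
#' @export
r_index_table <- function(profiles, table) {
  if (nrow(profiles) == 0) {
    return(data.frame(gene_id = character(0), age = character(0),
                      r_index = numeric(0), basal_cy3 = numeric(0),
                      direction = character(0), decile = integer(0),
                      stringsAsFactors = FALSE))
  }
  age <- profiles$age[1]
  basal <- basal_cy3_by_gene(table, age)
  fc_mat <- as.matrix(profiles[, c("fc3", "fc6", "fc12", "fc24")])
  out <- data.frame(
    gene_id = profiles$gene_id, age = age,
    r_index = vapply(seq_len(nrow(profiles)), function(i) {
      compute_r_index(fc_mat[i, ], basal[[profiles$gene_id[i]]])
    }, numeric(1)),
    basal_cy3 = unname(basal[profiles$gene_id]),
    direction = profiles$dominant_direction,
    decile = NA_integer_, stringsAsFactors = FALSE)
  rank_deciles(out)
}

#' Rank R-Index records into deciles within age x direction strata
#'
#' Records are sorted by decreasing absolute R-Index within each stratum
#' (ties broken by gene id for determinism); decile 1 holds the top 10%.
#' Strata with fewer than 10 records are still decile-labelled but a warning
#' notes that some bins are empty.
#'
#' @param records R-Index records ([r_index_table()] layout).
#' @return records with the `decile` column filled.
#' @export
rank_deciles <- function(records) {
  if (nrow(records) == 0) return(records)
  strata <- paste(records$age, records$direction)
  for (s in unique(strata)) {
    idx <- which(strata == s)
    n <- length(idx)
    if (n < 10) warning("stratum ", s, " has only ", n,
                        " record(s); some deciles are empty")
    ord <- idx[order(-abs(records$r_index[idx]), records$gene_id[idx])]
    records$decile[ord] <- as.integer(ceiling(10 * seq_len(n) / n))
  }
  records
}

#' Chi-square test of decile-count uniformity
#'
#' Compares the decile occupancy of a gene subset against the uniform
#' expectation (subset size / 10 per decile), Pearson chi-square with 9
#' degrees of freedom.
#'
#' @param counts integer vector of counts per decile (length 10).
#' @return list: `chi2`, `df`, `p`.
#' @export
decile_uniformity_test <- function(counts) {
  stopifnot(length(counts) == 10, all(counts >= 0))
  total <- sum(counts)
  if (total == 0) stop("empty subset: no decile counts to test")
  ht <- suppressWarnings(
    stats::chisq.test(counts, p = rep(1 / 10, 10), correct = FALSE))
  list(chi2 = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}
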