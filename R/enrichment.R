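#' One-sided Fisher over-representation test of a query list in a gene set
#'
#' The gene set is intersected with the background before testing; the
#' query must be a subset of the background. The p-value is the upper
#' hypergeometric tail P(X >= overlap) of the 2 x 2 table (overlap,
#' query-not-set, set-not-query, rest).
#'
#' @param query character vector of query gene ids.
#' @param gene_set a gene set (list with `name`, `members`, optionally
#'   `directions`), as from [read_gmt()].
#' @param background character vector: the gene universe (e.g. all genes
#'   passing the detection floor).
#' @return one-row data.frame: `set_name`, `n_overlap`, `list_size`,
#'   `set_size`, `background_size`, `p`, `fold_enrichment` (`q` and `z` are
#'   filled by [ora_collection()]).
#' @export
ora_fisher <- function(query, gene_set, background) {
  background <- unique(background)
  if (length(background) == 0) stop("empty background")
  query <- unique(query)
  if (!all(query %in% background)) {
    stop("query contains genes outside the background")
  }
  members <- intersect(unique(gene_set$members), background)
  k <- length(intersect(query, members))
  n <- length(query); K <- length(members); N <- length(background)
  p <- if (K == 0 || n == 0) 1 else
    stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  fold <- if (K == 0 || n == 0) 0 else (k / n) / (K / N)
  data.frame(set_name = gene_set$name, n_overlap = k, list_size = n,
             set_size = K, background_size = N, p = p,
             fold_enrichment = fold, q = NA_real_, z = NA_real_,
             stringsAsFactors = FALSE)
}

#' Over-representation analysis of a query list against a GMT collection
#'
#' Runs [ora_fisher()] per set, BH-adjusts p over the collection, and — for
#' directional sets and when observed directions are supplied — computes the
#' activation z-score.
#'
#' @param query character vector of query gene ids.
#' @param gene_sets list of gene sets ([read_gmt()]).
#' @param background gene universe.
#' @param observed_directions optional named vector (+1 induced / -1
#'   repressed) of the observed regulation direction per query gene.
#' @return data.frame, one row per set, with `q` (BH over the collection)
#'   and `z` filled; the per-set overlap gene lists are attached as the
#'   `overlap_genes` attribute (a named list), which
#'   [subtract_signature()] consumes.
#' @export
ora_collection <- function(query, gene_sets, background,
                           observed_directions = NULL) {
  rows <- lapply(gene_sets, function(s) ora_fisher(query, s, background))
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res$q <- bh_adjust(res$p)
  overlaps <- lapply(gene_sets, function(s) {
    intersect(unique(query), intersect(s$members, unique(background)))
  })
  names(overlaps) <- res$set_name
  if (!is.null(observed_directions)) {
    res$z <- vapply(seq_along(gene_sets), function(i) {
      s <- gene_sets[[i]]
      if (is.null(s$directions)) return(NA_real_)
      genes <- intersect(overlaps[[i]], names(s$directions))
      genes <- intersect(genes, names(observed_directions))
      activation_zscore(observed_directions[genes], s$directions[genes])
    }, numeric(1))
  }
  attr(res, "overlap_genes") <- overlaps
  res
}

#' Apply the reporting gates to enrichment results
#'
#' A result is reported when its overlap has at least `min_n` genes, its
#' BH-adjusted p is below `alpha`, and its FDR (the same BH-adjusted value)
#' is below `fdr_max`; with both gates on the adjusted value the binding
#' gate is `min(alpha, fdr_max)`. Pathway defaults are `alpha = 0.01`; the
#' GO variant uses `alpha = 0.001`.
#'
#' @param results [ora_collection()] output.
#' @param min_n minimum overlap size.
#' @param alpha adjusted-p gate.
#' @param fdr_max FDR gate.
#' @return the surviving rows (with `overlap_genes` attribute subset).
#' @export
filter_enriched <- function(results, min_n = 10, alpha = 0.01,
                            fdr_max = 0.10) {
  keep <- results$n_overlap >= min_n & results$q < alpha &
    results$q < fdr_max
  out <- results[keep, , drop = FALSE]
  rownames(out) <- NULL
  ov <- attr(results, "overlap_genes")
  if (!is.null(ov)) attr(out, "overlap_genes") <- ov[out$set_name]
  out
}

#' Subtract an acute-phase (or other) signature from enrichment overlaps
#'
#' Recomputes each result's overlap after removing the signature genes and
#' drops results whose residual overlap falls below `min_residual`. Both the
#' original and the residual overlap counts are reported, so enrichments
#' that merely recycle the signature can be told apart from independent
#' convergences.
#'
#' @param results [ora_collection()] output (needs the `overlap_genes`
#'   attribute).
#' @param signature character vector of signature gene ids.
#' @param min_residual minimum residual overlap.
#' @return surviving rows with an `n_residual` column.
#' @export
subtract_signature <- function(results, signature, min_residual = 5) {
  ov <- attr(results, "overlap_genes")
  if (is.null(ov)) stop("results carry no overlap gene lists")
  residual <- vapply(results$set_name, function(nm) {
    length(setdiff(ov[[nm]], signature))
  }, integer(1))
  results$n_residual <- residual
  keep <- residual >= min_residual
  out <- results[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "overlap_genes") <- ov[out$set_name]
  out
}

#' Directional-consistency activation z-score
#'
#' A transparent stand-in for curated activation scoring: each annotated
#' overlap gene contributes +1 when its observed regulation direction
#' matches the set's expected direction and -1 otherwise;
#' z = sum / sqrt(N). |z| >= 2 is conventionally read as a directional
#' (activated or inhibited) pathway.
#'
#' @param observed named vector of observed directions (+1 / -1).
#' @param expected named vector of expected directions (+1 / -1), aligned
#'   with `observed`.
#' @return z, or NA when no annotated overlap genes exist.
#' @export
activation_zscore <- function(observed, expected) {
  stopifnot(length(observed) == length(expected))
  if (length(observed) == 0) return(NA_real_)
  s <- ifelse(sign(observed) == sign(expected), 1, -1)
  sum(s) / sqrt(length(s))
}
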