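#' @keywords internal
"_PACKAGE"

#' Ages, time points and developmental intervals used throughout
#'
#' The design places the insult at postnatal day 5 (P5) or 10 (P10) and
#' samples the injured hemisphere 3, 6, 12 and 24 h later; basal development
#' is profiled at the four stages P2, P5, P10 and P15.
#' @name design-constants
NULL

#' @rdname design-constants
#' @export
HI_AGES <- c("P5", "P10")

#' @rdname design-constants
#' @export
HI_TIMES <- c(3L, 6L, 12L, 24L)

#' @rdname design-constants
#' @export
DEV_STAGES <- c("P2", "P5", "P10", "P15")

#' @rdname design-constants
#' @export
DEV_INTERVALS <- c("P2-P5", "P5-P10", "P10-P15", "P2-P15")

PROBE_TABLE_COLS <- c("probe_id", "gene_id", "age", "time_h", "condition",
                      "replicate", "cy3", "cy5")

#' Validate a probe-level signal table
#'
#' A probe table holds one row per probe x array. Two-color rows (the
#' hypoxia-ischemia contrasts) carry both channels: `cy3` is the naive
#' (control) signal and `cy5` the HI signal co-hybridised on the same array.
#' One-color developmental rows carry only `cy3` and have `time_h = NA`.
#'
#' @param table data.frame with columns `probe_id`, `gene_id`, `age`,
#'   `time_h`, `condition`, `replicate`, `cy3`, `cy5`.
#' @return the table, invisibly, after checking all invariants.
#' @export
validate_probe_table <- function(table) {
  missing <- setdiff(PROBE_TABLE_COLS, names(table))
  if (length(missing) > 0) {
    stop("probe table is missing column(s): ", paste(missing, collapse = ", "))
  }
  if (!all(table$age %in% DEV_STAGES)) {
    stop("age must be one of ", paste(DEV_STAGES, collapse = ", "))
  }
  two_color <- !is.na(table$time_h)
  if (!all(table$time_h[two_color] %in% HI_TIMES)) {
    stop("time_h must be one of ", paste(HI_TIMES, collapse = ", "), " or NA")
  }
  if (!all(table$condition %in% c("naive", "HI"))) {
    stop("condition must be 'naive' or 'HI'")
  }
  if (any(!is.finite(table$cy3)) || any(table$cy3 < 0)) {
    stop("cy3 signals must be finite and non-negative")
  }
  if (any(two_color & (!is.finite(table$cy5) | table$cy5 < 0))) {
    stop("cy5 signals must be finite and non-negative on two-color rows")
  }
  if (any(!two_color & !is.na(table$cy5))) {
    stop("cy5 must be NA on one-color (development) rows")
  }
  if (any(two_color & is.na(table$cy5))) {
    stop("cy5 must be present on two-color rows")
  }
  key <- paste(table$probe_id, table$age, table$time_h, table$condition,
               table$replicate, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- table$probe_id[duplicated(key)][1]
    stop("duplicate (probe, age, time, condition, replicate) key, e.g. probe ",
         dup)
  }
  invisible(table)
}

#' Read a tab-delimited probe-level signal table
#'
#' @param path path to a TSV file with a header row.
#' @param dialect optional named character vector mapping file column names to
#'   the canonical names (`probe_id`, `gene_id`, `age`, `time_h`, `condition`,
#'   `replicate`, `cy3`, `cy5`); entries are `c(file_name = "canonical")`.
#'   This is how Agilent Feature-Extraction exports with different headers are
#'   adapted — no parsing beyond column renaming is attempted.
#' @return a validated probe table (data.frame).
#' @export
read_probe_table <- function(path, dialect = NULL) {
  table <- utils::read.delim(path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE,
                             colClasses = "character", na.strings = "NA")
  if (!is.null(dialect)) {
    hit <- names(table) %in% names(dialect)
    names(table)[hit] <- unname(dialect[names(table)[hit]])
  }
  missing <- setdiff(PROBE_TABLE_COLS, names(table))
  if (length(missing) > 0) {
    stop("probe table file ", path, " is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  table <- table[PROBE_TABLE_COLS]
  for (col in c("time_h", "replicate")) {
    val <- suppressWarnings(as.integer(table[[col]]))
    bad <- !is.na(table[[col]]) & table[[col]] != "" & is.na(val)
    if (any(bad)) stop("unparseable ", col, " value: ", table[[col]][bad][1])
    table[[col]] <- val
  }
  for (col in c("cy3", "cy5")) {
    val <- suppressWarnings(as.numeric(table[[col]]))
    bad <- !is.na(table[[col]]) & table[[col]] != "" & is.na(val)
    if (any(bad)) stop("unparseable ", col, " signal: ", table[[col]][bad][1])
    table[[col]] <- val
  }
  table$gene_id[is.na(table$gene_id)] <- ""
  validate_probe_table(table)
  table
}

#' Write a probe table (or any stage output) as TSV
#'
#' Probabilities and fold changes are written with 6 significant digits so
#' that repeated runs with the same seed produce byte-identical files.
#'
#' @param table data.frame to write.
#' @param path output path.
#' @export
write_tsv <- function(table, path) {
  out <- table
  for (col in names(out)) {
    if (is.numeric(out[[col]]) && !is.integer(out[[col]])) {
      out[[col]] <- signif(out[[col]], 6)
    }
    if (is.logical(out[[col]])) out[[col]] <- ifelse(out[[col]], "TRUE", "FALSE")
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read a stage output written by [write_tsv()]
#' @param path TSV path.
#' @return data.frame.
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    na.strings = "NA")
}
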