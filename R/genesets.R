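#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, `name<TAB>description<TAB>member...`.
#' An extended dialect carries an expected regulation direction per member,
#' `gene:+1` (activation-consistent when induced) or `gene:-1`; these
#' annotations feed the activation z-score. Duplicate members are dropped.
#'
#' @param path GMT file path.
#' @return list of gene sets; each element has `name`, `source` (the
#'   description field), `members` (character vector) and `directions`
#'   (named numeric vector of +1/-1, or NULL for undirected sets).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- lapply(seq_along(lines), function(i) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      stop("malformed GMT line ", i, ": fewer than 3 tab-separated fields")
    }
    members <- fields[-(1:2)]
    members <- members[nzchar(members)]
    directional <- grepl(":[+-]1$", members)
    directions <- NULL
    if (all(directional) && length(members) > 0) {
      genes <- sub(":[+-]1$", "", members)
      directions <- ifelse(grepl(":\\+1$", members), 1, -1)
      names(directions) <- genes
      directions <- directions[!duplicated(genes)]
      members <- genes
    }
    members <- unique(members)
    if (length(members) == 0) {
      stop("gene set '", fields[1], "' (line ", i, ") has no members")
    }
    list(name = fields[1], source = fields[2], members = members,
         directions = directions)
  })
  names(sets) <- vapply(sets, `[[`, character(1), "name")
  sets
}

#' Write gene sets to a GMT file
#' @param sets list of gene sets as returned by [read_gmt()].
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(sets, function(s) {
    members <- s$members
    if (!is.null(s$directions)) {
      members <- paste0(names(s$directions),
                       ifelse(s$directions > 0, ":+1", ":-1"))
    }
    paste(c(s$name, s$source, members), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
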