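#' Read a pipeline run configuration (JSON or YAML)
#'
#' Any key absent from the file falls back to [default_config()].
#'
#' @param path `.json`, `.yaml` or `.yml` file.
#' @return configuration list.
#' @export
read_run_config <- function(path) {
  config <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  merge_config(default_config(), config)
}

merge_config <- function(base, override) {
  for (key in names(override)) {
    if (is.list(override[[key]]) && is.list(base[[key]])) {
      base[[key]] <- merge_config(base[[key]], override[[key]])
    } else {
      base[[key]] <- override[[key]]
    }
  }
  base
}

#' Default pipeline configuration
#'
#' @param seed integer seed driving the synthetic-data stages.
#' @param out_dir output directory for stage tables and the summary.
#' @return list with `sim` ([sim_params()] arguments), `thresholds`
#'   ([call_thresholds()] arguments), `center_ratios` (logical; off because
#'   inputs are assumed Lowess-normalised upstream), `gmt` (path to a gene-set
#'   file, or NULL to build demonstration sets from the simulated universe),
#'   `seed` and `out_dir`.
#' @export
default_config <- function(seed = 1L, out_dir = "results") {
  list(
    sim = list(seed = seed),
    thresholds = list(),
    center_ratios = FALSE,
    gmt = NULL,
    seed = seed,
    out_dir = out_dir
  )
}

log_stage <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}
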