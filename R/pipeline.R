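#' Demonstration gene sets drawn from a simulated gene universe
#'
#' Builds one directional set seeded with the planted cross-age core (so the
#' over-representation stage has a true positive to find) plus random filler
#' sets. Uses the current RNG stream, so a pipeline seed makes it
#' reproducible.
#'
#' @param universe character vector of gene ids.
#' @param core_genes gene ids to concentrate in the first set.
#' @param n_sets number of sets.
#' @param set_size members per set.
#' @return list of gene sets in [read_gmt()] layout.
#' @export
demo_gene_sets <- function(universe, core_genes, n_sets = 8, set_size = 50) {
  core_pick <- sample(core_genes, min(length(core_genes), set_size %/% 2))
  first_members <- unique(c(core_pick,
                            sample(universe, set_size - length(core_pick))))
  directions <- rep(1, length(first_members))
  names(directions) <- first_members
  sets <- list(list(name = "core_response", source = "synthetic",
                    members = first_members, directions = directions))
  for (i in seq_len(n_sets - 1)) {
    sets[[i + 1]] <- list(name = sprintf("random_set_%02d", i),
                          source = "synthetic",
                          members = sample(universe, set_size),
                          directions = NULL)
  }
  names(sets) <- vapply(sets, `[[`, character(1), "name")
  sets
}

#' Annotated genes detectable above the signal floor at one age
#'
#' A gene passes when at least one of its probes has a mean channel signal
#' at or above the floor in some contrast of the age. This is the
#' detectability universe: it serves as the enrichment background and as
#' the reference population for recovery statistics.
#'
#' @param table two-color probe table.
#' @param age `"P5"` or `"P10"`.
#' @param thresholds [call_thresholds()].
#' @return sorted character vector of gene ids.
#' @export
floor_passing_genes <- function(table, age, thresholds = call_thresholds()) {
  rows <- table[!is.na(table$time_h) & table$age == age &
                  nzchar(table$gene_id), ]
  key <- paste(rows$probe_id, rows$time_h)
  pass <- tapply(pmax(rows$cy3, rows$cy5), key, mean) >=
    thresholds$signal_floor
  sort(unique(rows$gene_id[match(names(pass)[pass], key)]))
}

#' Run the full analysis pipeline on synthetic data
#'
#' Stages, in order: simulate (two-color HI time course and one-color
#' developmental series with planted truth) -> optional ratio centering ->
#' HI calling -> probe-to-gene collapse -> kinetics classification ->
#' R-Index scoring and decile ranking -> cross-age partition -> ontogeny
#' interference -> gene-set over-representation. Every stage writes a TSV
#' under `config$out_dir` and contributes to `summary.json`. Identical
#' config and seed give byte-identical outputs.
#'
#' @param config configuration list (see [default_config()]) or a path to a
#'   JSON/YAML file.
#' @return the summary list, invisibly.
#' @export
run_pipeline <- function(config = default_config()) {
  if (is.character(config)) config <- read_run_config(config)
  config <- merge_config(default_config(), config)
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  thresholds <- do.call(call_thresholds, config$thresholds)
  summary <- list(seed = config$seed, thresholds = unclass(thresholds))
  timed <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) {
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    log_stage(stage, sprintf("done in %.1fs", proc.time()[["elapsed"]] - t0))
    res
  }

  # --- simulate -------------------------------------------------------------
  sim_args <- config$sim
  sim_args$seed <- config$seed
  params <- do.call(sim_params, sim_args)
  hi <- timed("simulate-hi", generate_hi_dataset(params))
  dev <- timed("simulate-dev", generate_dev_dataset(params))
  write_tsv(hi$probes, file.path(out_dir, "hi_probes.tsv"))
  write_tsv(hi$truth, file.path(out_dir, "hi_truth.tsv"))
  write_tsv(dev$probes, file.path(out_dir, "dev_probes.tsv"))
  write_tsv(dev$truth, file.path(out_dir, "dev_truth.tsv"))
  summary$n_probes <- length(unique(hi$probes$probe_id))
  summary$n_genes <- params$n_genes

  table <- hi$probes
  if (isTRUE(config$center_ratios)) {
    table <- timed("normalize", center_ratios(table))
  }

  # --- differential calling -------------------------------------------------
  hi_calls <- timed("call-hi", call_hi_all(table, thresholds))
  write_tsv(hi_calls, file.path(out_dir, "hi_calls.tsv"))
  summary$n_hi_call_records <- nrow(hi_calls)

  gene_calls <- timed("collapse", suppressMessages(collapse_probes(hi_calls)))
  write_tsv(gene_calls, file.path(out_dir, "gene_calls.tsv"))
  summary$n_gene_call_records <- nrow(gene_calls)

  # --- kinetics and R-Index -------------------------------------------------
  profiles <- timed("kinetics", {
    do.call(rbind, lapply(HI_AGES, function(a)
      kinetics_profiles(gene_calls, a)))
  })
  write_tsv(profiles, file.path(out_dir, "kinetics.tsv"))
  count_by <- function(df, ...) {
    if (nrow(df) == 0) return(list())
    tab <- table(interaction(df[c(...)], sep = "|", drop = TRUE))
    as.list(setNames(as.integer(tab), names(tab)))
  }
  summary$kinetics_counts <- count_by(profiles, "age", "kinetics")
  summary$direction_counts <- count_by(profiles, "age", "dominant_direction")
  summary$n_biphasic <- count_by(profiles[profiles$biphasic, , drop = FALSE],
                                 "age")

  rindex <- timed("r-index", {
    do.call(rbind, lapply(HI_AGES, function(a) {
      suppressWarnings(
        r_index_table(profiles[profiles$age == a, , drop = FALSE], table))
    }))
  })
  write_tsv(rindex, file.path(out_dir, "rindex.tsv"))

  # --- developmental calling ------------------------------------------------
  dev_changes <- timed("call-dev", {
    do.call(rbind, lapply(DEV_INTERVALS, function(iv)
      call_dev_changes(dev$probes, thresholds, iv)))
  })
  write_tsv(dev_changes, file.path(out_dir, "dev_changes.tsv"))
  dev_gene <- collapse_dev_changes(dev_changes)
  write_tsv(dev_gene, file.path(out_dir, "dev_gene_changes.tsv"))
  summary$n_dev_change_records <- nrow(dev_changes)
  summary$n_dev_genes <- length(unique(dev_gene$gene_id))

  # --- cross-age ------------------------------------------------------------
  prof5 <- profiles[profiles$age == "P5", , drop = FALSE]
  prof10 <- profiles[profiles$age == "P10", , drop = FALSE]
  cross <- timed("crossage", intersect_ages(prof5, prof10))
  write_tsv(cross$partition, file.path(out_dir, "crossage_partition.tsv"))
  overlap <- overlap_timecourse(gene_calls[gene_calls$age == "P5", ],
                                gene_calls[gene_calls$age == "P10", ])
  write_tsv(overlap$per_time, file.path(out_dir, "overlap_matrix.tsv"))
  write_tsv(overlap$persistence, file.path(out_dir, "persistence.tsv"))
  iso <- isochronous_subset(cross$partition, prof5, prof10)
  summary$crossage <- cross$summary
  summary$union_records <- cross$summary$n_union
  summary$common_pct_p5 <- cross$summary$common_pct_p5
  summary$common_pct_p10 <- cross$summary$common_pct_p10
  summary$n_isochronous <- length(iso)

  common_ind <- cross$partition$gene_id[cross$partition$status == "common" &
                                          cross$partition$dir_p5 == "induced"]
  summary$r2_inductions <- tryCatch({
    x <- prof5$max_abs_log2fc[match(common_ind, prof5$gene_id)]
    y <- prof10$max_abs_log2fc[match(common_ind, prof10$gene_id)]
    amplitude_correlation(x, y)$r2
  }, error = function(e) NA_real_)

  # --- ontogeny -------------------------------------------------------------
  coinc <- timed("ontogeny", {
    rbind(coincidence_classify(prof5, dev_gene, "P5"),
          coincidence_classify(prof10, dev_gene, "P10"))
  })
  write_tsv(coinc, file.path(out_dir, "coincidence.tsv"))
  waves <- transient_wave_detect(dev_gene)
  write_tsv(waves, file.path(out_dir, "dev_waves.tsv"))
  pct <- function(x) if (length(x) > 0) 100 * mean(x) else NA_real_
  summary$coincident_pct_p5 <- pct(coinc$coincident[coinc$age == "P5"])
  summary$coincident_pct_p10 <- pct(coinc$coincident[coinc$age == "P10"])
  ortho_antag <- vapply(HI_AGES, function(a) {
    c(ortho = sum(coinc$relation[coinc$age == a] == "ortho", na.rm = TRUE),
      antagonistic = sum(coinc$relation[coinc$age == a] == "antagonistic",
                         na.rm = TRUE))
  }, integer(2))
  summary$ortho_antag <- as.list(as.data.frame(ortho_antag))
  summary$wave_counts <- if (nrow(waves) > 0)
    as.list(table(waves$wave)) else list()

  # --- enrichment -----------------------------------------------------------
  enr <- timed("enrich", {
    background <- sort(union(floor_passing_genes(table, "P5", thresholds),
                             floor_passing_genes(table, "P10", thresholds)))
    core_truth <- unique(hi$truth$gene_id[hi$truth$in_core])
    sets <- if (is.null(config$gmt)) {
      demo_gene_sets(background, intersect(core_truth, background))
    } else {
      read_gmt(config$gmt)
    }
    query <- intersect(cross$partition$gene_id[
      cross$partition$status == "common"], background)
    obs <- setNames(ifelse(cross$partition$dir_p5 == "induced", 1, -1),
                    cross$partition$gene_id)
    res <- ora_collection(query, sets, background,
                          observed_directions = obs)
    list(all = res, kept = filter_enriched(res))
  })
  write_tsv(enr$all, file.path(out_dir, "enrichment.tsv"))
  summary$n_enriched_tested <- nrow(enr$all)
  summary$n_enriched_kept <- nrow(enr$kept)
  summary$enriched_sets <- enr$kept$set_name

  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE,
                       null = "null")
  log_stage("summary", "written to ", file.path(out_dir, "summary.json"))
  invisible(summary)
}
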