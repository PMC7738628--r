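#' Simulation parameters for synthetic microarray datasets
#'
#' Defaults emulate the study design the pipeline was built for: two ages
#' (P5, P10) sampled 3/6/12/24 h after the insult on 3 replicate two-color
#' arrays per contrast, and a one-color developmental series at P2/P5/P10/P15
#' with 8 replicate pools per stage. Basal intensities are log10-normal with
#' a low-signal tail below the 100-unit detection floor; replicate noise is
#' multiplicative log-normal per channel, which makes log-ratios Gaussian and
#' matches the t-test assumption of the calling rules.
#'
#' @param n_genes number of annotated genes.
#' @param multi_probe_fraction fraction of genes carried by 2-3 probes
#'   (the rest are singletons).
#' @param unannotated_fraction extra probes with no gene id, as a fraction of
#'   the annotated probe count; they ride through calling and are dropped at
#'   gene collapse.
#' @param n_replicates_hi replicate arrays per HI contrast.
#' @param n_replicates_dev replicate pools per developmental stage.
#' @param basal_log10_mean,basal_log10_sd log10-normal basal signal.
#' @param low_signal_fraction fraction of probes resampled to a basal signal
#'   between 10 and 100 units, below the detection floor.
#' @param frac_regulated fraction of genes regulated by HI at each age.
#' @param kinetics_mix named proportions over the four kinetic classes
#'   `early`, `transient`, `late`, `lasting`; must sum to 1.
#' @param amplitude_min_fc minimum planted linear fold change; amplitudes are
#'   drawn as `log2(fc) = log2(amplitude_min_fc) + Exp(amplitude_log2_rate)`
#'   so every planted regulation clears the calling thresholds with margin.
#' @param amplitude_log2_rate rate of the exponential log2-amplitude tail.
#' @param induced_fraction probability that a regulated gene is induced
#'   rather than repressed (default 0.6: inductions outnumber repressions
#'   60/40 in this kind of insult response).
#' @param shared_core_fraction fraction of each age's regulated genes that
#'   belong to the cross-age core: regulated at both ages, same direction,
#'   one shared amplitude draw (so cross-age amplitudes correlate strongly
#'   by construction).
#' @param biphasic_fraction fraction of regulated genes given opposite-sign
#'   regulation at an early and a late time point.
#' @param noise_cv coefficient of variation of the multiplicative log-normal
#'   replicate noise, per channel.
#' @param dev_frac_changed fraction of genes with a planted developmental
#'   trajectory change.
#' @param dev_transient_fraction fraction of changed genes whose trajectory
#'   reverses (up-then-down or down-then-up) instead of stepping once.
#' @param dev_amplitude_min_fc,dev_amplitude_log2_rate amplitude law of the
#'   developmental steps, as for the HI amplitudes.
#' @param seed integer RNG seed; the same seed reproduces the dataset
#'   byte for byte.
#' @return validated parameter list of class `sim_params`.
#' @export
sim_params <- function(n_genes = 1000L,
                       multi_probe_fraction = 0.10,
                       unannotated_fraction = 0.05,
                       n_replicates_hi = 3L,
                       n_replicates_dev = 8L,
                       basal_log10_mean = 2.8,
                       basal_log10_sd = 0.6,
                       low_signal_fraction = 0.10,
                       frac_regulated = 0.20,
                       kinetics_mix = c(early = 0.30, transient = 0.30,
                                        late = 0.20, lasting = 0.20),
                       amplitude_min_fc = 2.5,
                       amplitude_log2_rate = 1.5,
                       induced_fraction = 0.60,
                       shared_core_fraction = 0.35,
                       biphasic_fraction = 0.05,
                       noise_cv = 0.10,
                       dev_frac_changed = 0.10,
                       dev_transient_fraction = 0.30,
                       dev_amplitude_min_fc = 4.0,
                       dev_amplitude_log2_rate = 1.5,
                       seed = 1L) {
  params <- list(n_genes = as.integer(n_genes),
                 multi_probe_fraction = multi_probe_fraction,
                 unannotated_fraction = unannotated_fraction,
                 n_replicates_hi = as.integer(n_replicates_hi),
                 n_replicates_dev = as.integer(n_replicates_dev),
                 basal_log10_mean = basal_log10_mean,
                 basal_log10_sd = basal_log10_sd,
                 low_signal_fraction = low_signal_fraction,
                 frac_regulated = frac_regulated,
                 kinetics_mix = kinetics_mix,
                 amplitude_min_fc = amplitude_min_fc,
                 amplitude_log2_rate = amplitude_log2_rate,
                 induced_fraction = induced_fraction,
                 shared_core_fraction = shared_core_fraction,
                 biphasic_fraction = biphasic_fraction,
                 noise_cv = noise_cv,
                 dev_frac_changed = dev_frac_changed,
                 dev_transient_fraction = dev_transient_fraction,
                 dev_amplitude_min_fc = dev_amplitude_min_fc,
                 dev_amplitude_log2_rate = dev_amplitude_log2_rate,
                 seed = as.integer(seed))
  fracs <- c("multi_probe_fraction", "unannotated_fraction",
             "low_signal_fraction", "frac_regulated", "induced_fraction",
             "shared_core_fraction", "biphasic_fraction",
             "dev_frac_changed", "dev_transient_fraction")
  for (f in fracs) {
    if (params[[f]] < 0 || params[[f]] > 1) stop(f, " must be in [0, 1]")
  }
  if (!setequal(names(params$kinetics_mix),
                c("early", "transient", "late", "lasting"))) {
    stop("kinetics_mix must name early, transient, late, lasting")
  }
  if (abs(sum(params$kinetics_mix) - 1) > 1e-8) {
    stop("kinetics_mix must sum to 1")
  }
  if (params$amplitude_min_fc < 1.5 || params$dev_amplitude_min_fc < 2) {
    stop("planted amplitudes must clear the calling thresholds")
  }
  if (params$noise_cv < 0) stop("noise_cv must be non-negative")
  class(params) <- "sim_params"
  params
}

# multiplicative log-normal noise with unit mean and the requested CV
rlnoise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log1p(cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

ramplitude <- function(n, min_fc, rate) {
  2^(log2(min_fc) + stats::rexp(n, rate = rate))
}

# probe map shared by the two-color and one-color generators: gene ids,
# probes per gene, basal signal per probe (low tail resampled under the floor)
make_probe_map <- function(params) {
  genes <- sprintf("G%05d", seq_len(params$n_genes))
  n_probes_per_gene <- ifelse(
    stats::runif(params$n_genes) < params$multi_probe_fraction,
    sample(2:3, params$n_genes, replace = TRUE), 1L)
  gene_id <- rep(genes, n_probes_per_gene)
  probe_id <- paste0("A_", gene_id, "_",
                     unlist(lapply(n_probes_per_gene, seq_len)))
  n_extra <- round(params$unannotated_fraction * length(probe_id))
  if (n_extra > 0) {
    probe_id <- c(probe_id, sprintf("A_UNANN_%04d", seq_len(n_extra)))
    gene_id <- c(gene_id, rep("", n_extra))
  }
  basal <- 10^stats::rnorm(length(probe_id), params$basal_log10_mean,
                           params$basal_log10_sd)
  low <- stats::runif(length(probe_id)) < params$low_signal_fraction
  basal[low] <- 10^stats::runif(sum(low), 1, 2)
  data.frame(probe_id = probe_id, gene_id = gene_id, basal = basal,
             stringsAsFactors = FALSE)
}

# admissible detection patterns (3,6,12,24 h) for each kinetic class
class_patterns <- list(
  early     = rbind(c(1,0,0,0), c(1,1,0,0), c(1,0,1,0), c(1,1,1,0)),
  transient = rbind(c(0,1,0,0), c(0,0,1,0), c(0,1,1,0)),
  late      = rbind(c(0,0,0,1), c(0,1,0,1), c(0,0,1,1), c(0,1,1,1)),
  lasting   = rbind(c(1,0,0,1), c(1,1,0,1), c(1,0,1,1), c(1,1,1,1))
)

sample_pattern <- function(class) {
  pool <- class_patterns[[class]]
  pool[sample.int(nrow(pool), 1L), ] == 1
}

# truth rows for one age's regulated genes; biphasic genes get opposite signs
# at their first and last detected time points
plant_age_truth <- function(genes, age, direction, amplitude, params,
                            in_core) {
  n <- length(genes)
  if (n == 0) {
    return(data.frame(gene_id = character(0), age = character(0),
                      direction = character(0), kinetics = character(0),
                      biphasic = logical(0), in_core = logical(0),
                      p3 = logical(0), p6 = logical(0), p12 = logical(0),
                      p24 = logical(0), fc3 = numeric(0), fc6 = numeric(0),
                      fc12 = numeric(0), fc24 = numeric(0),
                      stringsAsFactors = FALSE))
  }
  class <- sample(names(params$kinetics_mix), n, replace = TRUE,
                  prob = params$kinetics_mix)
  biphasic <- stats::runif(n) < params$biphasic_fraction
  fc <- matrix(NA_real_, n, 4)
  pattern <- matrix(FALSE, n, 4)
  for (i in seq_len(n)) {
    pat <- if (biphasic[i]) sample_pattern("lasting") else
      sample_pattern(class[i])
    signs <- rep(direction[i], 4)
    if (biphasic[i]) {
      on <- which(pat)
      signs[on[length(on)]] <- -direction[i]
      class[i] <- classify_kinetics(pat)
    }
    pattern[i, ] <- pat
    fc[i, pat] <- signs[pat] * amplitude[i]
  }
  data.frame(gene_id = genes, age = age,
             direction = ifelse(direction > 0, "induced", "repressed"),
             kinetics = class, biphasic = biphasic, in_core = in_core,
             p3 = pattern[, 1], p6 = pattern[, 2], p12 = pattern[, 3],
             p24 = pattern[, 4],
             fc3 = fc[, 1], fc6 = fc[, 2], fc12 = fc[, 3], fc24 = fc[, 4],
             stringsAsFactors = FALSE)
}

#' Generate a two-color hypoxia-ischemia time-course dataset with known truth
#'
#' For each age x time point, 3 replicate arrays co-hybridise naive (Cy3)
#' against HI (Cy5) material. Unregulated genes have expected log-ratio 0;
#' a regulated gene's expected Cy5/Cy3 ratio equals its planted fold change
#' at the time points where its planted pattern is on. Cross-age core genes
#' are regulated at both ages in the same direction and reuse a single
#' amplitude draw, so their per-age amplitudes correlate by construction.
#'
#' @param params [sim_params()] list.
#' @return list with `probes` (a validated two-color probe table) and
#'   `truth` (one row per regulated gene x age: planted pattern, per-time
#'   signed fold changes, kinetics class, biphasic flag, core membership).
#' @export
generate_hi_dataset <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  map <- make_probe_map(params)
  genes <- unique(map$gene_id[nzchar(map$gene_id)])

  n_reg <- round(params$frac_regulated * params$n_genes)
  n_core <- round(params$shared_core_fraction * n_reg)
  core <- sample(genes, n_core)
  rest <- setdiff(genes, core)
  spec5 <- sample(rest, n_reg - n_core)
  spec10 <- sample(setdiff(rest, spec5), n_reg - n_core)

  dir_core <- ifelse(stats::runif(n_core) < params$induced_fraction, 1, -1)
  amp_core <- ramplitude(n_core, params$amplitude_min_fc,
                         params$amplitude_log2_rate)
  dir5 <- ifelse(stats::runif(length(spec5)) < params$induced_fraction, 1, -1)
  dir10 <- ifelse(stats::runif(length(spec10)) < params$induced_fraction, 1, -1)
  amp5 <- ramplitude(length(spec5), params$amplitude_min_fc,
                     params$amplitude_log2_rate)
  amp10 <- ramplitude(length(spec10), params$amplitude_min_fc,
                      params$amplitude_log2_rate)

  truth <- rbind(
    plant_age_truth(core, "P5", dir_core, amp_core, params, TRUE),
    plant_age_truth(spec5, "P5", dir5, amp5, params, FALSE),
    plant_age_truth(core, "P10", dir_core, amp_core, params, TRUE),
    plant_age_truth(spec10, "P10", dir10, amp10, params, FALSE))

  # expected Cy5/Cy3 ratio per gene x age x time (1 when unregulated)
  fc_cols <- c("fc3", "fc6", "fc12", "fc24")
  ratio_of <- function(gene_vec, age, time_idx) {
    r <- rep(1, length(gene_vec))
    rows <- truth[truth$age == age, c("gene_id", fc_cols[time_idx])]
    hit <- match(gene_vec, rows$gene_id)
    fc <- rows[[2]][hit]
    planted <- !is.na(hit) & !is.na(fc)
    r[planted] <- ifelse(fc[planted] > 0, fc[planted], -1 / fc[planted])
    r
  }

  grids <- list()
  for (age in HI_AGES) {
    for (ti in seq_along(HI_TIMES)) {
      ratio <- ratio_of(map$gene_id, age, ti)
      for (rep_i in seq_len(params$n_replicates_hi)) {
        cy3 <- map$basal * rlnoise(nrow(map), params$noise_cv)
        cy5 <- map$basal * ratio * rlnoise(nrow(map), params$noise_cv)
        grids[[length(grids) + 1L]] <- data.frame(
          probe_id = map$probe_id, gene_id = map$gene_id, age = age,
          time_h = HI_TIMES[ti], condition = "HI", replicate = rep_i,
          cy3 = cy3, cy5 = cy5, stringsAsFactors = FALSE)
      }
    }
  }
  probes <- do.call(rbind, grids)
  rownames(probes) <- NULL
  validate_probe_table(probes)
  list(probes = probes, truth = truth)
}

#' Generate a one-color developmental dataset with known truth
#'
#' Eight replicate pools per stage at P2, P5, P10 and P15. Changed genes
#' follow either a monotone trajectory (one step up or down at a random
#' interval, then stable) or a transient wave peaking (or dipping) at P5 or
#' P10, so that consecutive intervals reverse direction.
#'
#' @param params [sim_params()] list.
#' @return list with `probes` (one-color probe table: `cy5` is NA, `time_h`
#'   is NA) and `truth` (per changed gene: wave class and signed per-interval
#'   fold changes, NA where the planted level does not move).
#' @export
generate_dev_dataset <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed + 104729L)  # offset so HI and dev draws are independent
  map <- make_probe_map(params)
  genes <- unique(map$gene_id[nzchar(map$gene_id)])

  n_changed <- round(params$dev_frac_changed * params$n_genes)
  changed <- sample(genes, n_changed)
  transient <- stats::runif(n_changed) < params$dev_transient_fraction
  amp <- ramplitude(n_changed, params$dev_amplitude_min_fc,
                    params$dev_amplitude_log2_rate)
  up <- ifelse(stats::runif(n_changed) < 0.5, 1, -1)

  # stage levels relative to P2; columns P2, P5, P10, P15
  levels <- matrix(1, n_changed, 4, dimnames = list(changed, DEV_STAGES))
  wave <- rep("monotone", n_changed)
  for (i in seq_len(n_changed)) {
    a <- if (up[i] > 0) amp[i] else 1 / amp[i]
    if (transient[i]) {
      peak <- sample(c(2L, 3L), 1L)   # P5 or P10
      levels[i, peak] <- a
      wave[i] <- if (up[i] > 0) "up_down" else "down_up"
    } else {
      boundary <- sample(1:3, 1L)     # step after this stage index
      levels[i, (boundary + 1L):4L] <- a
    }
  }

  signed_fc <- function(r) ifelse(r >= 1, r, -1 / r)
  step <- function(j) {
    r <- levels[, j + 1L] / levels[, j]
    ifelse(abs(log2(r)) < 1e-12, NA_real_, signed_fc(r))
  }
  truth <- data.frame(
    gene_id = changed, wave = wave, transient = transient,
    fc_P2_P5 = step(1), fc_P5_P10 = step(2), fc_P10_P15 = step(3),
    fc_P2_P15 = ifelse(abs(log2(levels[, 4] / levels[, 1])) < 1e-12,
                       NA_real_, signed_fc(levels[, 4] / levels[, 1])),
    stringsAsFactors = FALSE)
  rownames(truth) <- NULL

  level_of <- function(gene_vec, stage) {
    l <- rep(1, length(gene_vec))
    hit <- match(gene_vec, changed)
    l[!is.na(hit)] <- levels[hit[!is.na(hit)], stage]
    l
  }
  grids <- list()
  for (stage in DEV_STAGES) {
    lev <- level_of(map$gene_id, stage)
    for (rep_i in seq_len(params$n_replicates_dev)) {
      grids[[length(grids) + 1L]] <- data.frame(
        probe_id = map$probe_id, gene_id = map$gene_id, age = stage,
        time_h = NA_integer_, condition = "naive", replicate = rep_i,
        cy3 = map$basal * lev * rlnoise(nrow(map), params$noise_cv),
        cy5 = NA_real_, stringsAsFactors = FALSE)
    }
  }
  probes <- do.call(rbind, grids)
  rownames(probes) <- NULL
  validate_probe_table(probes)
  list(probes = probes, truth = truth)
}

#' Generate a pure-noise dataset for type-I-error experiments
#'
#' @param params [sim_params()] list; `frac_regulated` / `dev_frac_changed`
#'   are forced to zero.
#' @param type `"two_color"` (HI design) or `"one_color"` (developmental
#'   design).
#' @return a probe table with no planted signal.
#' @export
make_null_dataset <- function(params = sim_params(),
                              type = c("two_color", "one_color")) {
  type <- match.arg(type)
  if (type == "two_color") {
    params$frac_regulated <- 0
    generate_hi_dataset(params)$probes
  } else {
    params$dev_frac_changed <- 0
    generate_dev_dataset(params)$probes
  }
}
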