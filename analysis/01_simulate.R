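#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study — a two-color HI time course at P5
# and P10 (3 replicate arrays x 4 time points) and a one-color developmental
# series at P2/P5/P10/P15 (8 replicate pools) — with planted ground truth.

suppressPackageStartupMessages(library(hitca))
dir.create("results/data", recursive = TRUE, showWarnings = FALSE)

params <- sim_params(seed = 7)
hi <- generate_hi_dataset(params)
dev <- generate_dev_dataset(params)

write_tsv(hi$probes, "results/data/hi_probes.tsv")
write_tsv(hi$truth, "results/data/hi_truth.tsv")
write_tsv(dev$probes, "results/data/dev_probes.tsv")
write_tsv(dev$truth, "results/data/dev_truth.tsv")

cat("HI dataset:", length(unique(hi$probes$probe_id)), "probes,",
    nrow(hi$probes), "rows;", nrow(hi$truth),
    "planted gene x age regulations\n")
cat("  planted induced fraction:",
    round(mean(hi$truth$direction == "induced"), 3), "\n")
cat("  planted core genes:", length(unique(hi$truth$gene_id[hi$truth$in_core])),
    "\n")
cat("Development dataset:", nrow(dev$probes), "rows;",
    nrow(dev$truth), "genes with planted trajectories (",
    sum(dev$truth$transient), "transient )\n")
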