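#!/usr/bin/env Rscript
# Stage 2: differential calling. Two-color HI contrasts are filtered by the
# 100-unit floor, then called by rule A (fold > 2 in >= 2 of 3 replicates)
# or rule B (mean fold > 1.5, BH t-test vs zero < 0.05); probes collapse to
# genes by largest amplitude. One-color stage pairs are called at |FC| >= 2,
# BH unpaired t < 0.001, twofold background.

suppressPackageStartupMessages(library(hitca))
hi_probes <- read_probe_table("results/data/hi_probes.tsv")
dev_probes <- read_probe_table("results/data/dev_probes.tsv")
thresholds <- call_thresholds()

hi_calls <- call_hi_all(hi_probes, thresholds)
gene_calls <- collapse_probes(hi_calls)
write_tsv(hi_calls, "results/hi_calls.tsv")
write_tsv(gene_calls, "results/gene_calls.tsv")

cat("Probe-level HI call records:", nrow(hi_calls), "\n")
print(table(age = hi_calls$age, rule = hi_calls$rule))
cat("Gene-level records after collapse:", nrow(gene_calls),
    "(", sum(gene_calls$splice_conflict), "splice-conflict records )\n")
cat("Direction split:",
    round(100 * mean(gene_calls$direction == "induced"), 1), "% induced\n")

dev_changes <- do.call(rbind, lapply(DEV_INTERVALS, function(iv)
  call_dev_changes(dev_probes, thresholds, iv)))
dev_gene <- collapse_dev_changes(dev_changes)
write_tsv(dev_changes, "results/dev_changes.tsv")
write_tsv(dev_gene, "results/dev_gene_changes.tsv")
cat("Developmental change records:", nrow(dev_changes), "on",
    length(unique(dev_gene$gene_id)), "genes\n")
print(table(interval = dev_gene$interval, direction =
              ifelse(dev_gene$fc > 0, "up", "down")))
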