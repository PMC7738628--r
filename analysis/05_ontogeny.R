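#!/usr/bin/env Rscript
# Stage 5: interference of the insult with spontaneous development —
# coincidence of HI-regulated genes with developmental changes in the
# flanking intervals, ortho/antagonistic direction, transient waves, and
# the contingency tests comparing the two ages.

suppressPackageStartupMessages(library(hitca))
profiles <- read_tsv("results/kinetics.tsv")
dev_gene <- read_tsv("results/dev_gene_changes.tsv")

coinc <- rbind(
  coincidence_classify(profiles[profiles$age == "P5", ], dev_gene, "P5"),
  coincidence_classify(profiles[profiles$age == "P10", ], dev_gene, "P10"))
write_tsv(coinc, "results/coincidence.tsv")

tab <- table(age = coinc$age, coincident = coinc$coincident)
print(tab)
for (a in c("P5", "P10")) {
  cat(sprintf("%s: %.1f%% of HI-regulated genes coincide with development\n",
              a, 100 * mean(coinc$coincident[coinc$age == a])))
}
if (all(dim(tab) == c(2, 2)) && all(rowSums(tab) > 0) && all(colSums(tab) > 0)) {
  chi <- contingency_test(matrix(tab, 2), "chi2")
  cat(sprintf("Coincidence by age: chi2 = %.1f, df = %d, p = %.3g\n",
              chi$statistic, chi$df, chi$p))
}

rel <- table(age = coinc$age[coinc$coincident],
             relation = coinc$relation[coinc$coincident])
print(rel)

waves <- transient_wave_detect(dev_gene)
write_tsv(waves, "results/dev_waves.tsv")
cat("Developmental trajectory classes (called, P5-P10 / P10-P15):\n")
print(table(waves$wave))
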