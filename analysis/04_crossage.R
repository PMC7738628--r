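#!/usr/bin/env Rscript
# Stage 4: cross-age structure — the common (core) response, age-specific
# and opposite-direction sets, isochronous genes, time-point overlap, and
# amplitude statistics across ages.

suppressPackageStartupMessages(library(hitca))
gene_calls <- read_tsv("results/gene_calls.tsv")
profiles <- read_tsv("results/kinetics.tsv")
prof5 <- profiles[profiles$age == "P5", ]
prof10 <- profiles[profiles$age == "P10", ]

cross <- intersect_ages(prof5, prof10)
write_tsv(cross$partition, "results/crossage_partition.tsv")
s <- cross$summary
cat("Regulated genes: P5 =", s$n_p5, ", P10 =", s$n_p10,
    ", union =", s$n_union, "\n")
cat("Common same-direction core:", s$n_common,
    sprintf("(%.1f%% of P5, %.1f%% of P10, %.1f%% of union)\n",
            s$common_pct_p5, s$common_pct_p10, s$common_pct_union))
cat("Opposite-direction genes:", s$n_opposite, "\n")

iso <- isochronous_subset(cross$partition, prof5, prof10)
cat("Isochronous genes (same kinetics class at both ages):", length(iso),
    "\n")

overlap <- overlap_timecourse(gene_calls[gene_calls$age == "P5", ],
                              gene_calls[gene_calls$age == "P10", ])
write_tsv(overlap$per_time, "results/overlap_matrix.tsv")
write_tsv(overlap$persistence, "results/persistence.tsv")

common_ind <- cross$partition$gene_id[cross$partition$status == "common" &
                                        cross$partition$dir_p5 == "induced"]
x <- prof5$max_abs_log2fc[match(common_ind, prof5$gene_id)]
y <- prof10$max_abs_log2fc[match(common_ind, prof10$gene_id)]
corr <- amplitude_correlation(x, y)
cat(sprintf("Cross-age amplitude correlation (inductions): r2 = %.3f, p = %.3g, n = %d\n",
            corr$r2, corr$p, corr$n))

rindex <- read_tsv("results/rindex.tsv")
ri5 <- rindex$r_index[rindex$age == "P5"][match(common_ind,
        rindex$gene_id[rindex$age == "P5"])]
ri10 <- rindex$r_index[rindex$age == "P10"][match(common_ind,
        rindex$gene_id[rindex$age == "P10"])]
ricorr <- amplitude_correlation(ri5, ri10)
cat(sprintf("Cross-age R-Index correlation (inductions): r2 = %.3f\n",
            ricorr$r2))

# do common genes carry larger amplitudes than age-specific ones?
spec5 <- cross$partition$gene_id[cross$partition$status == "p5_specific"]
mw <- compare_amplitudes(
  2^prof5$max_abs_log2fc[prof5$gene_id %in% common_ind],
  2^prof5$max_abs_log2fc[prof5$gene_id %in% spec5])
cat(sprintf("Common vs P5-specific |FC|: medians %.2f vs %.2f, U = %.0f, p = %.3g\n",
            mw$median_a, mw$median_b, mw$U, mw$p))
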