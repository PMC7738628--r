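# hitca — hypoxia-ischemia time-course transcriptome analysis

`hitca` re-implements, as a tested R package, the analysis pipeline of a
two-color microarray study of the neonatal mouse brain's transcriptional
response to hypoxia-ischemia (HI). The insult is applied at postnatal day 5
(P5, a model of the preterm human brain) or P10 (term neonate); injured
hemispheres are profiled 3, 6, 12 and 24 h later against age- and
time-matched naive controls (Cy5 = HI, Cy3 = naive, 3 replicate arrays per
contrast), and spontaneous development is profiled on one-color arrays at
P2/P5/P10/P15 (8 replicate pools per stage). The package is for
transcriptomics analysts who want these filtering rules, scores and
classifications as reusable, tested functions — and for anyone who wants to
validate such a pipeline end to end on synthetic data with planted ground
truth.

## What it computes

* **Differential calling** per age × time contrast, after a 100-unit
  detection floor, by two rules: fold > 2 in ≥ 2 of 3 replicates in the
  same direction (rule A), or geometric-mean fold > 1.5 with a one-sample
  t-test of replicate log2-ratios vs 0 surviving Benjamini–Hochberg at 0.05
  (rule B). Repressions are recorded as negative folds (−x ⇔ ratio 1/x).
  Multi-probe genes collapse to the largest-amplitude probe; opposite-sign
  probes are kept and flagged as putative splice conflicts.
* **Kinetics classes** per regulated gene: *early* (3 h, gone by 24 h),
  *transient* (6/12 h only), *late* (24 h, absent at 3 h), *lasting*
  (both endpoints), plus a biphasic flag for opposite-sign calls.
* **R-Index**, a regulation score integrating amplitude, duration and
  basal expression:
  `R = (Σ significant signed FC over the 4 time points) × log10(basal Cy3)`,
  ranked into deciles within each age × direction stratum.
* **Cross-age structure**: the common (core) response — genes regulated at
  both ages in the same direction — age-specific and opposite-direction
  sets, isochronous genes, per-time-point overlap, Pearson r² of cross-age
  amplitudes, Mann–Whitney amplitude comparisons.
* **Developmental interference**: one-color stage-pair calling (|FC| ≥ 2,
  BH p < 0.001, twofold background), coincidence of HI effects with
  flanking developmental intervals, ortho/antagonistic direction calls,
  transient developmental waves, chi-square and Fisher contingency tests.
* **Over-representation analysis** against GMT collections: one-sided
  Fisher test on a detectability-conditioned background, BH FDR, the
  reporting gates N ≥ 10 / adjusted p < 0.01 / FDR < 10%, signature
  subtraction, and a directional activation z-score
  (`z = Σ±1/√N`) for sets annotated `gene:+1` / `gene:-1`.
* **Synthetic data** (`generate_hi_dataset()`, `generate_dev_dataset()`,
  `make_null_dataset()`): log-normal basal signal with a sub-floor tail,
  multiplicative replicate noise, planted regulations in the four kinetics
  classes, biphasic genes, multi-probe genes, a shared cross-age core and
  monotone/transient developmental trajectories — with the ground truth
  returned alongside the signals.

## Worked example

```r
library(hitca)

params <- sim_params(seed = 7)          # 1,000 genes, defaults
hi     <- generate_hi_dataset(params)

calls      <- call_hi_all(hi$probes, call_thresholds())
gene_calls <- collapse_probes(calls)
profiles   <- rbind(kinetics_profiles(gene_calls, "P5"),
                    kinetics_profiles(gene_calls, "P10"))
cross      <- intersect_ages(profiles[profiles$age == "P5", ],
                             profiles[profiles$age == "P10", ])
cross$summary[c("n_p5", "n_p10", "n_union", "n_common",
                "common_pct_p5", "common_pct_p10")]
```

On this dataset the run prints:

```
Probe-level HI call records: 885
Gene-level records after collapse: 770
Regulated genes: P5 = 185 , P10 = 182 , union = 303
Common same-direction core: 63 (34.1% of P5, 34.6% of P10, 20.8% of union)
Cross-age amplitude correlation (inductions): r2 = 0.906, p = 4.41e-20, n = 38
```

Read: of 1,000 genes, 185 were called HI-regulated at P5 and 182 at P10;
63 genes respond at both ages in the same direction (about a third of each
age's list — the age-independent core), and among core inductions the
per-age amplitudes agree strongly (r² = 0.906), as expected since core
genes share one planted amplitude. The planted core had 70 genes; the 7
missing ones sit below the 100-unit detection floor, which the calling
rules silence by design.

The `analysis/` directory holds the same workflow as numbered stage
scripts; run them in order from the repository root:

```sh
Rscript analysis/01_simulate.R        # synthetic datasets + truth tables
Rscript analysis/02_call_differential.R
Rscript analysis/03_kinetics_rindex.R
Rscript analysis/04_crossage.R
Rscript analysis/05_ontogeny.R
Rscript analysis/06_enrichment.R
```

Each writes its tables under `results/` and prints what it found.

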