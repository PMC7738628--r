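---
title: "Methods: calling, kinetics, R-Index and cross-age analysis of a neonatal hypoxia-ischemia time course"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: calling, kinetics, R-Index and cross-age analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hitca)
```

## The experimental design the package models

Neonatal hypoxia-ischemia (HI) in the mouse — carotid ligation plus
hypoxia at postnatal day 5 (P5, modelling the preterm human brain) or P10
(modelling the term neonate) — triggers a transcriptional response that is
profiled here on two-color microarrays. Each contrast co-hybridises
HI-injured hemisphere material (Cy5 channel) against age- and time-matched
naive material (Cy3 channel) on 3 replicate arrays, at 3, 6, 12 and 24 h
after the insult. Spontaneous developmental expression is profiled on
one-color arrays at the four stages P2, P5, P10 and P15 with 8 replicate
pools per stage. Input tables are assumed Lowess-normalised upstream; an
optional per-array median-centering hook (`center_ratios()`) is provided
and off by default.

The package answers, on this design, the questions a time-course insult
study asks: which genes respond and in which direction; with what kinetics
(early, transient, late, lasting) and amplitude; which responses are
shared between the two ages (the core response) and which are
age-specific; how the insult interferes with the spontaneous developmental
program; and which curated gene sets are over-represented in the response.

## Differential calling

A probe enters analysis only if at least one of its mean channel signals
reaches the 100-unit detection floor — "both channels below 100" excludes
the probe. Two complementary rules then call a probe in one age x time
contrast:

* **Rule A (replicated fold):** the per-replicate Cy5/Cy3 fold exceeds 2
  in the same direction in at least 2 of 3 replicates, with the sign of
  the mean log-ratio agreeing. No p-value is attached.
* **Rule B (tested fold):** the geometric-mean fold exceeds 1.5 and a
  one-sample t-test of the replicate log2-ratios against zero survives
  Benjamini-Hochberg adjustment at 0.05.

The reported fold change is the signed linear fold of the geometric-mean
ratio; repressions are negative (−x means a ratio of 1/x). Every reported
call satisfies |FC| ≥ 1.5, so the rare rule-A probe whose geometric mean
falls below 1.5 (two strong replicates, one strong reversal) is dropped.

Design choices where more than one reading was possible:

* *t-test construction.* With 3 co-hybridised arrays the only coherent
  "t-test against zero" is a one-sample t on per-replicate log-ratios
  (df = 2); that is what is implemented. Zero replicate variance with a
  non-zero mean is treated as p = 0 (the replicates agree exactly).
* *BH family.* Adjustment runs over all floor-passing probes of one
  age x time contrast. Each comparison is processed as its own family,
  matching how per-comparison volcano workflows treat the data; the
  alternative (one family across all 8 contrasts) would couple contrasts
  through each other's p-value distributions.
* *Rule-A direction.* The 2 qualifying replicates must agree in
  direction; a 2-of-3 count mixing an induction with a repression never
  fires.
* *Floor logic.* "Below the floor in the two fluorochromes" is read as
  AND: a probe is excluded only when both channel means are low, so a
  strong induction from a silent baseline (Cy3 < 100, Cy5 ≥ 100) stays in.

Genes measured by several probes collapse to the probe with the largest
absolute log2 fold per gene x age x time. When two probes of one gene are
called in opposite directions at the same contrast, the strongest probe of
each direction is retained and both records carry a `splice_conflict`
flag — opposite signals on distinct probes of one gene suggest transcript
isoforms, and averaging them away would hide that. Probes without a gene
annotation ride through probe-level calling and are dropped (with a
logged count) at gene collapse.

Developmental changes between two stages require: mean signal of at least
200 units (twice the floor) in one stage; an absolute fold of stage means
of at least 2; and a BH-adjusted equal-variance unpaired t-test on log2
signals below 0.001. The pooled (equal-variance) t on the log scale is
the classical choice for 8-vs-8 pools of comparable dispersion.

## Kinetics classes and the R-Index

Each regulated gene's detection pattern over 3/6/12/24 h maps
deterministically onto four classes: **lasting** (detected at both 3 h
and 24 h — gaps between the endpoints are tolerated, since intermittent
detection at intermediate points reflects threshold crossings, not a new
kinetic regime), **early** (at 3 h, gone by 24 h), **late** (at 24 h,
absent at 3 h), **transient** (only 6 and/or 12 h). The four classes
partition all 15 non-empty patterns; the mapping is verified by
enumeration in the test suite. A gene with significant calls of both
signs across the time course is flagged **biphasic**.

The R-Index integrates amplitude, duration and basal expression:

R-Index = (Σ significant signed FC over the 4 time points) × log10(basal Cy3)

Signed linear folds enter the sum (repressions negative), so biphasic
genes partially cancel — the literal reading of the formula, kept
deliberately. Basal Cy3 is the geometric mean of the gene's naive-channel
signals across the age's four time-matched contrasts (all probes and
replicates pooled); the geometric mean is the natural location parameter
for log-normal intensities. A basal signal at or below 1 would make the
log10 weight non-positive and is rejected as an error. R-Indexes are
ranked into deciles within each age x direction stratum, decile 1 holding
the top 10% of |R-Index|; ties break lexicographically by gene id so runs
are reproducible. Occupancy of the deciles by a gene subset is compared
to uniformity with a Pearson chi-square (df = 9).

## Cross-age structure

Genes regulated at both ages with the same dominant direction form the
**common core**; direction consistency is required because a handful of
genes flip sign between ages and lumping them into the core would blur
its interpretation — they are reported separately as `opposite`.
Percentages are reported against each age's list and against the union,
since both denominators are informative. **Isochronous** genes are core
genes with an identical kinetics class at both ages (biphasic genes
excluded). Cross-age amplitude agreement is quantified by Pearson
correlation of the per-age maximal |log2 FC| (and of R-Indexes), reported
as r²; amplitude distributions are compared with a two-sided Mann-Whitney
U (normal approximation with tie correction), alongside medians and
interquartile ranges.

## Interference with spontaneous development

Each insult age has two flanking developmental intervals (P5: P2–P5 and
P5–P10; P10: P5–P10 and P10–P15). An HI-regulated gene is **coincident**
when it also changes significantly in either flanking interval; it is
**ortho** when the HI direction matches the developmental direction of
the reference interval and **antagonistic** otherwise. When both flanking
intervals are significant with conflicting signs, the subsequent interval
is the reference — the insult is read against the expression program it
anticipates; the reference interval is recorded per gene so the opposite
convention can be recomputed from the output table. Trajectories over two
consecutive intervals are classed `up_down`, `down_up`, or `monotone`
(same sign twice, or a change in exactly one interval). Contingency
comparisons use Pearson chi-square without Yates correction, or the
two-sided Fisher exact test for 2x2 tables.

## Over-representation analysis

Enrichment of a query list in a gene-set collection uses the one-sided
Fisher exact (upper hypergeometric tail) after intersecting each set with
the background. Plain Fisher is used rather than the EASE-style
(overlap − 1) deflation, for transparency. The background is the
**detectability universe**: all annotated genes with at least one
floor-passing probe at the relevant age(s), not the whole genome —
enrichment should condition on what the platform could have detected.
Reporting gates follow the convention of overlap ≥ 10, adjusted p below
0.01 (0.001 for the GO-style variant) and FDR below 10%; both the
"Benjamini-corrected p" and the "FDR" gate act on the same BH-adjusted
value here, so the binding gate is the smaller of the two — both are kept
in the interface because collections adjusted by other means keep the
two gates distinct. A signature-subtraction step recomputes overlaps
after removing a user-supplied signature (e.g. an acute-phase response
list) and drops results with fewer than 5 residual genes, to avoid
reporting the same stress module under many names. For directional sets
(`gene:+1` / `gene:-1` in the extended GMT dialect) a simple
directional-consistency z-score, z = Σ±1/√N, summarises whether the
overlap moves with (+) or against (−) the set's expected direction;
|z| ≥ 2 is read as directional. This is a deliberate simplification of
weighted literature-derived activation scores.

## The synthetic-data generator

`generate_hi_dataset()` and `generate_dev_dataset()` create datasets in
which every downstream claim can be checked against planted truth.

* **Basal intensities** are log10-normal (mean 2.8, sd 0.6 on the log10
  scale — i.e. centred near 630 units with a wide spread), with 10% of
  probes resampled between 10 and 100 units. That sub-floor tail exists
  to exercise the detection floor, not to be recovered.
* **Noise** is multiplicative log-normal per replicate and channel with
  coefficient of variation 0.10, which makes log-ratios Gaussian — the
  assumption of the calling t-tests. Pooling variance across animals is
  not modelled separately; it is folded into this CV.
* **Regulations:** 20% of genes per age, induced with probability 0.6
  (inductions outnumber repressions roughly 60/40 in insult responses of
  this kind). Kinetic classes are drawn at proportions
  0.30/0.30/0.20/0.20 (early/transient/late/lasting) and a concrete
  detection pattern consistent with the class is drawn uniformly.
  Amplitudes are drawn as log2 FC = log2(2.5) + Exp(rate 1.5), so every
  planted regulation clears the calling thresholds with margin while
  keeping a realistic right tail. 5% of regulated genes are biphasic
  (opposite signs at their first and last detected time points).
* **Cross-age core:** 35% of each age's regulated genes are shared,
  same direction, reusing a single amplitude draw with independent
  per-age noise — so cross-age amplitude correlation is high by
  construction and the correlation machinery has signal to find.
* **Probes:** 90% of genes are singletons, 10% carry 2–3 probes; 5%
  extra probes are unannotated.
* **Development:** 10% of genes change, 30% of those transiently
  (peak or dip at P5 or P10, reversing between consecutive intervals),
  the rest stepping once; steps are at least 4-fold so that 8-vs-8
  comparisons at p < 0.001 detect them reliably.

What the generator does **not** emulate: dye bias and dye swaps, spatial
or print-tip artefacts, probe-sequence effects, correlated gene modules,
sex differences, and intensity-dependent variance. Passing the planted
recovery tests therefore demonstrates that the pipeline's logic is
correct under its own statistical assumptions — not that real arrays meet
those assumptions; on real data the Lowess normalisation and replicate
design upstream are doing work the generator skips.

Recovery statistics (kinetics-label recovery, core sensitivity and FDR)
are measured among planted genes whose probes pass the detection floor.
Genes planted below the floor are silenced by the filtering rules by
design — the same conditioning that defines the enrichment background. At
the default dataset (1,000 genes, seed 7) the floor-passing kinetics
recovery is ~99% and core sensitivity ~0.98 with zero false discoveries.

## Numerical conventions and degenerate inputs

* Probabilities and fold changes are written to TSV with 6 significant
  digits; identical configuration and seed reproduce every output file
  byte for byte.
* Decile ties break by gene id; strata with fewer than 10 records are
  ranked with a warning that some deciles are empty.
* Thresholds set to impossible values empty every downstream table
  without error: empty call lists propagate through kinetics, R-Index,
  cross-age and ontogeny stages as zero-row tables, and pipeline summary
  fields that need data (e.g. the cross-age r²) become NA.
* A chi-square or Fisher input with a zero marginal row/column, an
  amplitude vector with zero variance, and an empty decile subset are
  rejected with explicit errors rather than returning NaN.
* Problem sizes in the test suite were chosen to keep each check sharp
  at interactive cost: 1,000-gene datasets for recovery, 20,000 probes
  for the null false-positive experiment, 200 random ≤30-probe tables
  for oracle equivalence.

## Known limitations

* No Lowess/loess normalisation is included; inputs are taken as
  normalised (only median centering is offered).
* No moderated-variance (empirical-Bayes) statistics: the calling rules
  are deliberately the plain ones they re-implement, and with df = 2 the
  one-sample t of rule B has little power — on the default synthetic
  data almost all calls come from rule A. That mirrors the behaviour of
  the original thresholds rather than a weakness of the implementation.
* The activation z-score weighs every annotated gene equally; it is not
  a substitute for curated causal-network scoring.
* Gene identities are synthetic; the package reproduces the *procedures*
  and their operating characteristics, not the published gene lists,
  which would require the original hybridisations.
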