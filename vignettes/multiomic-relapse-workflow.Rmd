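---
title: "Methods: multi-omic analysis of paired primary/relapsed oligodendroglioma"
author: "gliomaRelapse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-omic analysis of paired primary/relapsed oligodendroglioma}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gliomaRelapse)
```

# Scope

`gliomaRelapse` implements, as tested and reusable functions, the analysis
stages of a paired tumor-relapse study of 1p/19q-codeleted diffuse glioma
(oligodendroglioma): somatic-variant filtering with a cross-patient
artifact test, trinucleotide mutational signatures with POLE hypermutator
scoring, coverage-based copy number with arm-level and focal calls,
structural-variant (SV) filtering with intragenic-rearrangement
annotation, DNA-methylation probe-to-gene collapse, WHO-2021 molecular
subtype classification, and expression-stratified survival analysis.
Because raw patient-level sequencing data of such studies are not
publicly distributable, the package ships a synthetic-data generator that
plants exactly the statistical structure each stage is designed to
recover; every stage is exercised and validated on that substrate.

The numbered scripts under `analysis/` run the stages as a narrative
workflow writing tables to `results/`; all computation lives in the
package so the test suite and `scripts/acceptance.R` exercise the same
code paths.

# Somatic-variant filtering

A candidate call is kept when it has at least 3 unique supporting reads
and a variant allele fraction (VAF) of at least 10% — both boundaries
inclusive (`filter_by_support()`).

The distinctive step is the **cross-patient artifact test**
(`artifact_chisq()`). Recurrent technical artifacts of a processing
pipeline reappear across unrelated patients at a characteristic allele
fraction, whereas a genuine somatic event is private to one patient. For
each variant, alternate and reference reads are pooled per patient over
that patient's primary and relapse samples, and the null hypothesis that
*every patient shares one underlying allele fraction* is tested with the
plain Pearson chi-square of the resulting 2 × P table:
statistic $\sum (O - E)^2 / E$ over both cells of every patient, $P - 1$
degrees of freedom. Only variants with *heterogeneous* fractions (p below
`alpha`) are retained. Conventions: a patient with zero pooled reads is
excluded; cells with zero expectation contribute zero; a pooled fraction
of exactly 0 or 1 gives statistic 0 and p 1. The significance threshold
is not dictated by the underlying study design, so it is exposed as
`alpha` with default 0.01 — small enough that, at the simulated depths,
binomial noise in a genuinely shared stratum is rarely mistaken for
heterogeneity, while a private clonal variant at depth ~60 yields
overwhelming evidence. Germline exclusion (`filter_germline()`) is
allele-exact against a sites-only blacklist.

# Mutational signatures and the POLE hypermutator

Single-nucleotide substitutions are tabulated over the 96 trinucleotide
channels in the pyrimidine-reference convention (purine-reference calls
are reverse-complemented), formatted `5'[ref>alt]3'`. The POLE
exonuclease-deficiency score is the fraction of mutations in the three
channels `T[C>A]T`, `T[C>T]G`, `T[T>G]T` (TCT>TAT, TCG>TTG, TTT>TGT). A
sample is flagged as a hypermutator when it carries at least
`min_mutations = 500` mutations *and* a POLE score of at least
`min_score = 0.2`. No principled cutoffs exist for these two numbers;
they were chosen once to separate a relapse with on the order of a
thousand signature-dominated mutations from an ordinary tumor with under
a hundred, and are configuration parameters, not constants.

# Copy number from coverage windows

Aligned-read counts in fixed 1000 bp windows (BED-style 0-based
half-open; terminal partial windows kept) are compared between tumor and
matched normal after library-size normalization:
$\log_2\big((t_w/T)\,/\,(n_w/N)\big)$ with $T, N$ the genome-wide totals.
Windows with a zero normal count are masked; windows with a zero tumor
count are masked as well so that every unmasked ratio is finite (a true
homozygous loss at adequate depth still surfaces through its neighbours).

Noise suppression is **median decimation**: consecutive blocks of
`factor` windows collapse to their median (masked values excluded; the
terminal partial block uses its own median). Two resolutions are used:

* factor 200 (200 kb blocks) for arm-level calling — each arm's call is
  the median of its unmasked block medians, `loss` at or below −0.3,
  `gain` at or above +0.3. The thresholds assume a largely pure tumor: a
  clonal one-copy loss sits near −1, a 1.5× gain near +0.58, so ±0.3
  tolerates substantial noise and some impurity while never calling
  diploid arms. The 1p/19q codeletion requires `loss` on both arms.
* factor 5 (5 kb blocks) for focal-deletion detection — at per-window
  depth ~60 a single 1 kb window crosses the −1 threshold by Poisson
  chance with probability ≈ 3 × 10⁻³, enough to occasionally interrupt
  or spuriously extend single-window runs; 5-window medians make both
  failure modes negligible while leaving tens-of-kb events at full
  contrast. Events shorter than one block are not detectable at this
  resolution, which is acceptable for promoter-scale (tens of kb)
  deletions.

`focal_deletions()` reports maximal runs of consecutive windows at or
below `del_thr = −1` whose span does not exceed `max_span = 3 Mb`
(excluding arm-scale losses), overlapped with gene spans;
`tss_overlap` marks runs covering the transcription start site — the
event class that inactivates a gene by removing its promoter-proximal
start.

# Structural variants

Breakpoints follow the BEDPE convention (0-based, orientation per
breakpoint from paired-end evidence). Filters:

* support: at least 5 unique reads (inclusive);
* cohort recurrence: removed only when matching SVs — both breakpoints
  within `match_window = 100` bp, identical orientations — occur in
  *strictly more than* 30% of cohort samples, so 3/10 survives and 4/10
  does not. The matching window is a modelling choice: breakpoint
  re-estimation across samples jitters by a few reads' worth of bases,
  while 100 bp is far below the distance between unrelated events;
* cohort-level evidence (for TCGA-style tables): junction-spanning read
  fraction ≥ 0.2 **or** at least 4 variant read pairs (inclusive OR,
  the plain reading of the rule); records missing both fields are
  rejected with a warning and counted.

An SV is **intragenic** when both breakpoints fall inside one gene's
span. With breakpoints ordered (orientations travelling with their
breakpoints), `(+,−)` is a deletion, `(−,+)` a duplication, `(+,+)` /
`(−,−)` an inversion; interchromosomal records are `other`. The
classification uses breakpoint orientations only and is independent of
the gene's strand. For deletions, exons fully contained in the deleted
interval are listed in transcript order and the event is in-frame when
the summed coding length removed is divisible by three; for other
classes the overlapped exons are listed and frame status is not
applicable.

# Methylation probe-to-gene collapse

Array probes mapping to one gene are reduced to a single per-sample beta
series in three steps:

1. variance filter — keep probes with across-sample variance *strictly*
   above 0.01 (a probe exactly at the threshold is removed);
2. cluster the surviving probes by Spearman correlation distance
   (1 − ρ, midranks for ties) with average-linkage hierarchical
   clustering cut into `k = 2` clusters. The cluster count is a design
   choice: promoter-associated probes (whose methylation silences the
   gene) versus gene-body/other probes is the canonical two-way split,
   and the selection rule below only needs the anticorrelated group
   isolated; `k` is configurable;
3. per cluster, correlate the per-sample *median* beta with the gene's
   expression (Spearman) and choose the most negative cluster; its
   median-beta series represents the gene. Ties are broken by larger
   cluster, then input order, for determinism. If no cluster correlates
   negatively the gene's methylation is flagged undefined rather than
   guessed.

Binary methylation status thresholds the representative beta at
`beta_cutoff = 0.3`, a conventional boundary between unmethylated
(< 0.2–0.3) and methylated states on beta-value arrays; it is exposed in
the configuration.

# WHO-2021 subtype classification

With tri-state markers (`TRUE`/`FALSE`/unknown): IDH-mutant with 1p/19q
codeletion → oligodendroglioma; IDH-mutant without → IDH-mutant
astrocytoma; IDH-wildtype with grade 4 *or* combined chromosome 7 gain
and chromosome 10 loss *or* TERT promoter mutation *or* EGFR
amplification → IDH-wildtype glioblastoma (the molecular
reclassification of lower-grade IDHwt tumors); remaining IDH-wildtype
grade 2/3 cases are `unclassified` and excluded from cohort analyses. An
unknown marker that would be decisive yields `unclassified` rather than a
guess; unknown IDH status is an error because the primary split cannot be
made. The 7+/10− criterion is evaluated at whole-chromosome level when
arm-level calls are supplied (both arms consistent), matching the
"chromosome 7 gain and chromosome 10 loss" reading.

# Survival and cohort statistics

The product-limit (Kaplan–Meier) estimator and the two-group log-rank
test are implemented from first principles — per event time the observed
events in one group are compared with their hypergeometric expectation
and variance, the statistic $(\sum O - \sum E)^2 / \sum V$ referred to
$\chi^2_1$ — so each term is directly checkable against hand tabulation;
the `survival` package serves as an independent cross-check in the test
suite, never as the implementation. Median survival is the smallest time
with $S(t) \le 0.5$.

Expression dichotomization: `low` is *strictly below* the cutoff (a value
equal to the cutoff is `high`), matching the "below X" phrasing of
expression-stratified analyses; cutoffs are either the cohort mean or a
fixed value (the workflow uses 7.8 for CNTNAP2 and 10.5 for PTPRD as its
fixed strata, and cohort means otherwise). The combined risk group is
`low/low` — low in both genes — versus everything else.

Wilcoxon rank-sum comparisons use midranks with tie correction, exact
enumeration when the pooled size is at most 20 without ties and the
continuity-corrected normal approximation otherwise (asymptotic at
cohort sizes, exact in small constructed cases). Fisher's exact test for
2 × 2 tables uses the conditional hypergeometric two-sided
probability-mass rule and reports the sample odds ratio $ad/bc$
(infinite when $bc = 0$). P-values are reported raw, without
multiple-testing correction, as is conventional for this kind of
descriptive cohort characterization.

# The synthetic-data generator

`simulation_config()` fixes the study conditions; its defaults *are* the
conditions under which the package's claims are tested:

* five patients with paired primary/relapse tumors; 92 truncal somatic
  SNVs per patient (the mutation load of a non-hypermutated tumor in
  this setting) at patient-specific VAFs uniform on 0.2–0.6, depth
  Poisson with mean 60;
* an artifact stratum of 30 variants present in *every* patient with
  counts binomial at one common allele fraction (0.5), plus 15 shared
  germline variants that also populate the blacklist, plus per-sample
  decoys pinned below the support/VAF thresholds;
* one hypermutator patient whose relapse carries 12 times the truncal
  load, with 80% of that patient's mutations drawn from genomic sites
  whose context matches the three POLE channels — the primary therefore
  also shows the signature at low load, as a seeding subclone would;
* coverage tracks realizing copy ratio 0.5 on 1p and 19q, 1.5 on both
  chr7 arms (all tumors), and a 50 kb focal deletion at ratio 0.25
  covering the PTPRD TSS (relapse samples);
* planted intragenic CNTNAP2 events — a deletion spanning exons 2–8 in
  patient 1's relapse, an intronic inversion in patient 2's — above the
  support threshold, sub-threshold decoy SVs, and a recurrent junction
  artifact present in every sample (removed only by the recurrence
  filter);
* a TCGA-like cohort (default 300 cases; 581 when emulating the full
  cohort) with subtype proportions 151:227:203
  (oligodendroglioma : astrocytoma : glioblastoma), marker expression
  decreasing by `grade_effect = 1` log2 unit per grade, exponential
  survival with baseline median 36 months and hazard ratio 3 for the
  below-mean-expression group, and independent uniform censoring whose
  upper bound is solved numerically to hit the target censoring rate
  (20%) — the simplest generator satisfying proportional hazards;
* per gene, 10 methylation probes: 5 anticorrelated with expression
  (monotone in the expression ranks, plus Gaussian noise, sd 0.05) and 5
  driven by a latent factor independent of expression. The second
  cluster is *coherent* rather than mutually independent noise: fully
  independent probes have no joint structure for a two-way average-
  linkage cut to recover, and the two-block design is what the collapse
  procedure assumes (promoter-like vs other probes). Both blocks pass
  the 0.01 variance filter by construction.

All randomness flows from the single `seed`; identical configurations
reproduce outputs exactly, and the generator restores the caller's RNG
state. The toy genome (chr1, chr7, chr10, chr19; ~9 Mb of uniform random
sequence from a fixed internal seed) is large enough for 200-fold
decimation to leave several blocks per arm, and hosts the two focal-event
genes on chr10, whose arms carry no planted arm event, so focal and
arm-level signals never confound each other.

What the generator does **not** emulate — and hence what passing tests do
not demonstrate about real data: alignment and mappability artifacts, GC
bias, tumor impurity and subclonal copy-number mixtures, array batch
effects and bimodal beta distributions, non-proportional hazards, and
correlated noise across probes or windows. The recovery rates measured
here are upper bounds that real data would erode.

# Validation strategy and problem sizes

The test suite validates each statistic against an independent oracle:
the artifact chi-square against `chisq.test` on 1000 random 2 × P
tables; Wilcoxon against full permutation enumeration for every size
pair with pooled n ≤ 12; Fisher against explicit hypergeometric
enumeration of all 2 × 2 tables with total ≤ 12; the product-limit
curve and log-rank statistic against hand-tabulated cases and the
`survival` package. Planted-event recovery is measured over 50
simulation seeds (arm events, focal TSS deletion, intragenic SV classes,
decoy exclusion), methylation cluster recovery over 50 seeds at noise sd
0.05 with 200-sample cohorts, log-rank null calibration over 200
replicate null cohorts of 100 cases (Kolmogorov–Smirnov uniformity), and
power over 100 replicate 300-case cohorts at hazard ratio 3 with 20%
censoring. These sizes were chosen so each estimate is stable to a few
percent while the whole suite stays comfortably interactive.

# Known limitations

* Tumor purity and ploidy are not modelled; arm-call thresholds assume
  high purity.
* No GC/mappability correction and no segmentation (HMM/CBS); focal
  detection is thresholded run-finding at block resolution.
* SV detection itself (from reads) is out of scope; the pipeline starts
  from candidate records.
* The methylation collapse assumes at most one gene per probe and a
  two-cluster structure by default.
* Differential expression is reduced to median-of-ratios normalization
  and per-gene paired fold changes (with a pseudo-count of one when a
  zero is involved); no dispersion modelling or inference.
* Survival analysis is unadjusted two-group comparison; no Cox
  modelling or covariate adjustment.
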