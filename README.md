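# gliomaRelapse

Multi-omic analysis of paired primary/relapsed 1p/19q-codeleted diffuse
glioma (oligodendroglioma), implemented as a tested R package plus a
numbered analysis workflow.

Oligodendrogliomas — IDH-mutant, 1p/19q-codeleted gliomas — can relapse
as far more aggressive tumors. Characterizing what changed at relapse
requires a chain of genomic analyses, each with sharp filtering rules:
separating true somatic mutations from recurrent technical artifacts,
recognizing a POLE-driven hypermutator by its trinucleotide signature,
calling arm-level and focal copy-number events from coverage, filtering
structural variants down to intragenic rearrangements, collapsing
methylation probes to gene-level values, classifying tumors by WHO-2021
molecular criteria, and testing whether low expression of candidate
suppressor genes predicts poor survival. This package implements that
chain for analysts who want each rule explicit, tested, and reusable,
with a synthetic-data generator standing in for patient-level data that
cannot be shared.

## The statistics at the core

**Cross-patient artifact test.** For a variant with per-patient pooled
alt/total read counts $(a_i, t_i)$, the null "one shared allele
fraction" is tested with the Pearson chi-square of the 2 × P table:
$f = \sum a_i / \sum t_i$,
$X^2 = \sum_i \frac{(a_i - f t_i)^2}{f t_i} + \frac{((t_i - a_i) - (1-f) t_i)^2}{(1-f) t_i}$,
with $P-1$ df. Calls are kept only when the fractions are heterogeneous
(p < α): genuine patient-private events, not shared artifacts.

**POLE hypermutator score.** Fraction of SNVs in the pyrimidine-strand
channels `T[C>A]T`, `T[C>T]G`, `T[T>G]T` (TCT>TAT, TCG>TTG, TTT>TGT).

**Copy number.** Per 1 kb window, $\log_2((t_w/T)/(n_w/N))$ against a
matched normal, median-decimated 200-fold for arm calls (loss ≤ −0.3,
gain ≥ +0.3; 1p/19q codeletion = loss on both arms) and 5-fold for focal
TSS deletions (runs ≤ −1 spanning ≤ 3 Mb).

**Rearrangements.** ≥ 5 unique reads; removed if matched (±100 bp, same
orientations) in > 30% of cohort samples; intragenic iff both
breakpoints fall in one gene's span, with orientation pairs (+,−)/(−,+)/
(+,+ or −,−) read as deletion/duplication/inversion.

**Methylation collapse.** Probes with variance > 0.01 are clustered by
Spearman distance (average linkage, k = 2); the cluster whose median
beta correlates most negatively with the gene's expression represents
the gene.

**Survival.** Kaplan–Meier product-limit curves and the two-group
log-rank test, written from first principles
($(\sum O - \sum E)^2/\sum V$ against $\chi^2_1$), with expression
dichotomized strictly below a cohort-mean or fixed cutoff.

## Worked example

The workflow scripts run the whole study on the synthetic cohort:

```sh
Rscript analysis/01_simulate.R          # generate all inputs (seed 1)
Rscript analysis/02_filter_variants.R   # support / germline / artifact filters
Rscript analysis/03_signatures.R        # 96-channel signatures, POLE score
Rscript analysis/04_copy_number.R       # log-ratio tracks, arm + focal calls
Rscript analysis/05_rearrangements.R    # SV filters, intragenic annotation
Rscript analysis/06_methylation.R       # probe-to-gene collapse
Rscript analysis/07_cohort_analysis.R   # WHO-2021, Wilcoxon, survival
```

Stage 02 prints the filtering cascade over 10 samples (5 patients,
primary + relapse):

```
support filter: 2482 -> 2377 calls
germline blacklist: 2377 -> 2227 calls
cross-patient artifact test (alpha 0.01): 2227 -> 1927 calls
```

Stage 03 identifies the planted hypermutator — note the signature
already visible at low load in the same patient's primary tumor:

```
          sample_id total pole_score hypermutator
3  patient2_primary    91 0.78021978        FALSE
4  patient2_relapse  1103 0.78241160         TRUE
patient2_relapse is a POLE hypermutator: 1103 mutations (12.1-fold over
its primary), POLE-channel fraction 0.78
```

Stage 04 calls the 1p/19q codeletion in 10/10 samples, the chr7 gain,
and the focal PTPRD TSS deletion in every relapse; stage 05 reduces 42
SV records to the two planted intragenic CNTNAP2 events:

```
         sample_id gene_id event_class         exons in_frame
1 patient1_relapse CNTNAP2    deletion 2,3,4,5,6,7,8     TRUE
2 patient2_relapse CNTNAP2   inversion  8,9,10,11,12       NA
```

Stage 06 selects the expression-anticorrelated probe cluster for 8/8
genes (ρ between −0.98 and −0.99), and stage 07 classifies the cohort,
shows marker expression falling with grade (Wilcoxon p down to 1e−29 at
n = 300) and low-expression groups with significantly worse survival.
`run_pipeline()` performs the same end to end with a checksummed output
manifest.

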