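#!/usr/bin/env Rscript
# Stage 01 — generate the study inputs.
#
# Simulates the paired primary/relapse cohort (5 patients, one POLE
# hypermutator, 1p/19q loss + chr7 gain, PTPRD TSS focal deletion,
# intragenic CNTNAP2 deletion/inversion) and the TCGA-like cohort tables,
# and writes them in the formats the downstream stages read: per-sample
# VCFs, a sites-only germline blacklist, coverage bedGraphs, a headered
# BEDPE, and TSV matrices.

library(gliomaRelapse)

seed <- 1L
out <- "results/01_inputs"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- simulation_config(seed = seed)
bundle <- simulate_paired_cohort(cfg)
cohort <- simulate_tcga_like_tables(cfg)

for (sid in unique(bundle$variants$sample_id))
  write_variant_vcf(bundle$variants[bundle$variants$sample_id == sid, ],
                    file.path(out, paste0(sid, ".vcf")))
write_site_blacklist(bundle$blacklist, file.path(out, "blacklist.vcf"))
write_tsv(bundle$cohort_counts, file.path(out, "cohort_counts.tsv"))
write_tsv(bundle$samples, file.path(out, "samples.tsv"))
write_tsv(bundle$variants, file.path(out, "variants_truth.tsv"))

write_bedgraph(bundle$coverage$normal, file.path(out, "normal.bedGraph"),
               name = "matched normal coverage")
for (sid in names(bundle$coverage$tumor))
  write_bedgraph(bundle$coverage$tumor[[sid]],
                 file.path(out, paste0(sid, ".coverage.bedGraph")),
                 name = paste(sid, "coverage"))

write_bedpe(bundle$svs, file.path(out, "rearrangements.bedpe"))
write_tsv(bundle$svs[, c("sv_id", "class")],
          file.path(out, "sv_truth.tsv"))

write_tsv(data.frame(gene_id = rownames(cohort$expression),
                     cohort$expression, check.names = FALSE),
          file.path(out, "expression.tsv"))
write_tsv(data.frame(probe_id = rownames(cohort$methylation),
                     cohort$methylation, check.names = FALSE),
          file.path(out, "methylation.tsv"))
write_tsv(cohort$probe_map, file.path(out, "probe_map.tsv"))
write_tsv(cohort$clinical, file.path(out, "clinical.tsv"))

cat(sprintf("simulated %d variant calls across %d samples, %d SV records,\n",
            nrow(bundle$variants), nrow(bundle$samples),
            nrow(bundle$svs)))
cat(sprintf("and a %d-case cohort (%d genes, %d probes); seed %d.\n",
            ncol(cohort$expression), nrow(cohort$expression),
            nrow(cohort$methylation), seed))
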