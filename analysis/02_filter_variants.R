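#!/usr/bin/env Rscript
# Stage 02 — somatic-variant filtering.
#
# Reads the per-sample VCFs, applies the support/VAF thresholds (>= 3 unique
# supporting reads, VAF >= 10%), removes gnomAD-style blacklisted germline
# sites, and removes cross-cohort technical artifacts with the per-variant
# chi-squared test for a shared allele fraction across patients.

library(gliomaRelapse)

in_dir <- "results/01_inputs"
out <- "results/02_variants"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

samples <- read_tsv(file.path(in_dir, "samples.tsv"))
calls <- do.call(rbind, lapply(samples$sample_id, function(sid) {
  v <- read_variant_vcf(file.path(in_dir, paste0(sid, ".vcf")))
  v$patient_id <- samples$patient_id[samples$sample_id == sid]
  v$timepoint <- samples$timepoint[samples$sample_id == sid]
  v
}))
blacklist <- read_site_blacklist(file.path(in_dir, "blacklist.vcf"))
cohort_counts <- read_tsv(file.path(in_dir, "cohort_counts.tsv"))

n0 <- nrow(calls)
calls <- filter_by_support(calls, min_alt = 3L, min_vaf = 0.10)
n1 <- nrow(calls)
calls <- filter_germline(calls, blacklist)
n2 <- nrow(calls)
calls <- filter_artifacts(calls, cohort_counts, alpha = 0.01)
n3 <- nrow(calls)

write_tsv(calls, file.path(out, "somatic_calls.tsv"))
write_tsv(attr(calls, "audit"), file.path(out, "artifact_audit.tsv"))

cat(sprintf("support filter: %d -> %d calls\n", n0, n1))
cat(sprintf("germline blacklist: %d -> %d calls\n", n1, n2))
cat(sprintf("cross-patient artifact test (alpha 0.01): %d -> %d calls\n",
            n2, n3))
cat("per-sample somatic burden:\n")
print(table(calls$sample_id))
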