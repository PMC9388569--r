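#!/usr/bin/env Rscript
# Stage 07 — WHO-2021 classification, expression statistics and survival.
#
# Assigns molecular subtypes (including the reclassification of lower-grade
# IDH-wildtype tumors with molecular glioblastoma features), compares
# marker expression between grades with Wilcoxon rank-sum tests, and
# stratifies overall survival by CNTNAP2/PTPRD expression: cohort-mean
# cutoffs, the fixed cutoffs 7.8 / 10.5, and the combined low/low group.
# Also assembles the oncoprint-style alteration summary for the paired
# tumors.

library(gliomaRelapse)

in_dir <- "results/01_inputs"
out <- "results/07_cohort"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

clinical <- read_tsv(file.path(in_dir, "clinical.tsv"))
expr_df <- read_tsv(file.path(in_dir, "expression.tsv"))
expr <- as.matrix(expr_df[, -1]); rownames(expr) <- expr_df$gene_id

clinical$who2021 <- classify_who2021(clinical)
write_tsv(clinical, file.path(out, "clinical_classified.tsv"))
cat("WHO-2021 subtype counts:\n")
print(subtype_counts(clinical$who2021))

time <- stats::setNames(clinical$time_months, clinical$case_id)
event <- stats::setNames(clinical$event, clinical$case_id)

comp <- list()
for (g in c("CNTNAP2", "PTPRD")) {
  v <- expr[g, clinical$case_id]
  row <- survival_by_expression(v, time, event, "mean")
  comp[[length(comp) + 1L]] <-
    cbind(data.frame(comparison = paste0(g, "_mean_cutoff")), row)
}
la <- dichotomize_expression(expr["CNTNAP2", clinical$case_id], "fixed",
                             fixed_cutoff = 7.8)$labels
lb <- dichotomize_expression(expr["PTPRD", clinical$case_id], "fixed",
                             fixed_cutoff = 10.5)$labels
cmb <- combined_low_group(la, lb)
ll <- cmb == "low/low"
if (any(ll) && !all(ll)) {
  lr <- logrank_test(time[ll], event[ll], time[!ll], event[!ll])
  comp[[length(comp) + 1L]] <- data.frame(
    comparison = "combined_lowlow_7.8_10.5", cutoff = NA, n_low = sum(ll),
    n_high = sum(!ll), statistic = lr$statistic, p = lr$p,
    median_low = attr(km_estimate(time[ll], event[ll]), "median"),
    median_high = attr(km_estimate(time[!ll], event[!ll]), "median"))
}
surv_tab <- do.call(rbind, comp)
write_tsv(surv_tab, file.path(out, "survival_comparisons.tsv"))
cat("\nsurvival comparisons (log-rank):\n")
print(surv_tab)

wilc <- list()
for (g in c("CNTNAP2", "PTPRD")) {
  for (pair in list(c(2, 3), c(3, 4), c(2, 4))) {
    a <- expr[g, clinical$case_id[clinical$grade == pair[1]]]
    b <- expr[g, clinical$case_id[clinical$grade == pair[2]]]
    if (length(a) && length(b)) {
      w <- wilcoxon_rank_sum(a, b)
      wilc[[length(wilc) + 1L]] <- data.frame(
        gene = g, grades = paste(pair, collapse = "v"), n_a = length(a),
        n_b = length(b), statistic = w$statistic, p = w$p)
    }
  }
}
wilc_tab <- do.call(rbind, wilc)
write_tsv(wilc_tab, file.path(out, "grade_wilcoxon.tsv"))
cat("\nexpression by grade (Wilcoxon rank-sum):\n")
print(wilc_tab)

# oncoprint over the paired tumors, from the stage outputs
focal <- read_tsv("results/04_copy_number/focal_deletions.tsv")
intragenic <- read_tsv("results/05_rearrangements/intragenic_rearrangements.tsv")
samples <- read_tsv(file.path(in_dir, "samples.tsv"))
alt <- rbind(
  if (nrow(focal)) data.frame(
    gene_id = focal$gene_id[focal$tss_overlap],
    sample_id = focal$sample_id[focal$tss_overlap],
    alteration = "focal_deletion_TSS") else NULL,
  if (nrow(intragenic)) data.frame(
    gene_id = intragenic$gene_id, sample_id = intragenic$sample_id,
    alteration = paste0("intragenic_", intragenic$event_class)) else NULL)
op <- oncoprint_table(alt, genes = toy_genes()$gene_id,
                      samples = samples$sample_id)
write_tsv(op, file.path(out, "oncoprint.tsv"))
cat("\noncoprint summary written; altered genes:\n")
print(op[apply(op[, -1] != "", 1, any), , drop = FALSE])
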