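#!/usr/bin/env Rscript
# Stage 04 — coverage-based copy number.
#
# Computes tumor/normal log2 ratio tracks from the 1 kb window counts,
# median-decimates 200-fold for arm-level calling (1p/19q codeletion, chr7
# gain) and 5-fold for focal-deletion detection at gene TSSs, and exports
# IGV-loadable bedGraph tracks.

library(gliomaRelapse)

in_dir <- "results/01_inputs"
out <- "results/04_copy_number"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

samples <- read_tsv(file.path(in_dir, "samples.tsv"))
normal <- read_bedgraph(file.path(in_dir, "normal.bedGraph"),
                        value = "count")

arm_rows <- list(); focal_rows <- list()
for (sid in samples$sample_id) {
  tumor <- read_bedgraph(file.path(in_dir,
                                   paste0(sid, ".coverage.bedGraph")),
                         value = "count")
  lr <- log_ratio(tumor, normal)
  dec <- median_decimate(lr, 200L)
  write_bedgraph(dec, file.path(out, paste0(sid, ".logratio.bedGraph")),
                 name = paste(sid, "log2 ratio (200x decimated)"))
  ac <- arm_summary(dec)
  ac$sample_id <- sid
  ac$codeletion_1p19q <- detect_codeletion(ac)
  arm_rows[[sid]] <- ac
  fd <- focal_deletions(median_decimate(lr, 5L))
  if (nrow(fd)) { fd$sample_id <- sid; focal_rows[[sid]] <- fd }
}

arm_calls <- do.call(rbind, arm_rows); rownames(arm_calls) <- NULL
write_tsv(arm_calls, file.path(out, "arm_calls.tsv"))
focal <- if (length(focal_rows)) do.call(rbind, focal_rows) else
  data.frame()
write_tsv(focal, file.path(out, "focal_deletions.tsv"))

cat("arm-level calls (decimated medians, thresholds +/-0.3):\n")
print(stats::aggregate(call ~ arm, arm_calls,
                       function(x) paste(unique(x), collapse = "/")))
cat(sprintf("1p/19q codeletion in %d/%d samples\n",
            sum(arm_calls$codeletion_1p19q[!duplicated(
              arm_calls$sample_id)]),
            nrow(samples)))
if (nrow(focal)) {
  cat("focal deletions overlapping genes:\n")
  print(focal[, c("sample_id", "gene_id", "start", "end", "tss_overlap")])
}
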