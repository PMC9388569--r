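#!/usr/bin/env Rscript
# Stage 05 — structural variants.
#
# Filters the BEDPE records by unique-read support (>= 5) and cohort
# recurrence (present in over 30% of samples, matched within 100 bp with
# identical orientations), annotates intragenic events by breakpoint
# orientation, and lists the exons removed by intragenic deletions with
# their reading-frame status.

library(gliomaRelapse)

in_dir <- "results/01_inputs"
out <- "results/05_rearrangements"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

svs <- read_bedpe(file.path(in_dir, "rearrangements.bedpe"))
samples <- read_tsv(file.path(in_dir, "samples.tsv"))

n0 <- nrow(svs)
kept <- filter_sv_support(svs, min_reads = 5L)
n1 <- nrow(kept)
kept <- filter_sv_recurrent(kept, svs, max_fraction = 0.30,
                            match_window = 100L,
                            n_samples = nrow(samples))
n2 <- nrow(kept)
cat(sprintf("support filter: %d -> %d; recurrence filter: %d -> %d\n",
            n0, n1, n1, n2))

ann <- annotate_intragenic(kept)
if (nrow(ann)) {
  extra <- do.call(rbind, lapply(seq_len(nrow(ann)), function(i) {
    ev <- ann[i, ]
    ae <- affected_exons(min(ev$pos1, ev$pos2), max(ev$pos1, ev$pos2),
                         gene_model(ev$gene_id), ev$event_class)
    data.frame(exons = paste(ae$exons, collapse = ","),
               in_frame = if (is.na(ae$in_frame)) NA else ae$in_frame)
  }))
  ann <- cbind(ann, extra)
}
write_tsv(ann, file.path(out, "intragenic_rearrangements.tsv"))

cat("intragenic rearrangements after filtering:\n")
print(ann[, c("sample_id", "gene_id", "event_class", "exons", "in_frame")])
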