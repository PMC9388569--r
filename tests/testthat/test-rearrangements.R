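test_that("unique-read support threshold is inclusive at 5", {
  svs <- rbind(sv_record(unique_reads = 5L), sv_record(unique_reads = 4L),
               sv_record(unique_reads = 20L))
  expect_equal(filter_sv_support(svs)$unique_reads, c(5L, 20L))
  expect_equal(nrow(filter_sv_support(svs[0, ])), 0L)
})

test_that("cohort recurrence removes only strictly-over-threshold SVs", {
  sv <- sv_record(pos1 = 10000L, pos2 = 90000L)
  cohort4 <- do.call(rbind, lapply(1:4, function(i) {
    r <- sv; r$sample_id <- paste0("c", i)
    r$pos1 <- r$pos1 + sample(-50:50, 1L); r
  }))
  cohort3 <- cohort4[1:3, ]
  # 4/10 samples (0.4 > 0.3): removed
  expect_equal(nrow(filter_sv_recurrent(sv, cohort4, n_samples = 10L)), 0L)
  # 3/10 samples (0.3 not over 0.3): retained
  expect_equal(nrow(filter_sv_recurrent(sv, cohort3, n_samples = 10L)), 1L)
  # breakpoints outside the match window do not count
  far <- cohort4; far$pos1 <- far$pos1 + 1000L
  expect_equal(nrow(filter_sv_recurrent(sv, far, n_samples = 10L)), 1L)
  # orientation must match
  flip <- cohort4; flip$strand1 <- "-"
  expect_equal(nrow(filter_sv_recurrent(sv, flip, n_samples = 10L)), 1L)
  # empty cohort leaves the input unchanged
  expect_equal(nrow(filter_sv_recurrent(sv, sv[0, ], n_samples = 10L)), 1L)
})

test_that("junction-evidence filter is an inclusive OR of the two criteria", {
  svs <- rbind(
    sv_record(junction_fraction = 0.20, variant_read_pairs = 0L),
    sv_record(junction_fraction = 0.10, variant_read_pairs = 4L),
    sv_record(junction_fraction = 0.19, variant_read_pairs = 3L))
  kept <- filter_sv_tcga(svs)
  expect_equal(nrow(kept), 2L)
  # one field may be missing as long as the other passes
  na_jf <- sv_record(junction_fraction = NA, variant_read_pairs = 6L)
  expect_equal(nrow(filter_sv_tcga(na_jf)), 1L)
  # both missing: rejected with a warning, and counted
  both_na <- sv_record(junction_fraction = NA, variant_read_pairs = NA)
  expect_warning(out <- filter_sv_tcga(rbind(svs, both_na)), "missing both")
  expect_equal(attr(out, "rejected_missing"), 1L)
  expect_equal(nrow(out), 2L)
})

test_that("orientation pairs map to the standard event classes", {
  expect_equal(classify_sv("chr1", 100L, "+", "chr1", 900L, "-"), "deletion")
  expect_equal(classify_sv("chr1", 100L, "-", "chr1", 900L, "+"),
               "duplication")
  expect_equal(classify_sv("chr1", 100L, "+", "chr1", 900L, "+"),
               "inversion")
  expect_equal(classify_sv("chr1", 100L, "-", "chr1", 900L, "-"),
               "inversion")
  expect_equal(classify_sv("chr1", 100L, "+", "chr2", 900L, "-"), "other")
  # breakpoint order is canonicalized with orientations travelling along
  expect_equal(classify_sv("chr1", 900L, "-", "chr1", 100L, "+"), "deletion")
})

test_that("intragenic annotation requires both breakpoints inside the span", {
  genes <- data.frame(gene_id = c("G1", "G2"),
                      chrom = c("chr1", "chr1"),
                      start = c(1000L, 50000L), end = c(20000L, 90000L),
                      strand = c("+", "-"), tss = c(1000L, 90000L))
  inside <- sv_record(pos1 = 2000L, pos2 = 15000L)
  outside <- sv_record(pos1 = 2000L, pos2 = 30000L)
  ann <- annotate_intragenic(rbind(inside, outside), genes)
  expect_equal(nrow(ann), 1L)
  expect_equal(ann$gene_id, "G1")
  expect_equal(ann$event_class, "deletion")
  # classification ignores the gene's strand
  ann2 <- annotate_intragenic(
    sv_record(pos1 = 60000L, pos2 = 80000L, strand1 = "+", strand2 = "+"),
    genes)
  expect_equal(ann2$event_class, "inversion")
  expect_equal(ann2$gene_id, "G2")
  # empty result keeps the schema
  none <- annotate_intragenic(sv_record(chrom1 = "chrX", chrom2 = "chrX"),
                              genes)
  expect_equal(nrow(none), 0L)
  expect_true(all(c("gene_id", "event_class") %in% names(none)))
})

test_that("affected exons and frame status follow coding lengths", {
  g <- micro_gene()
  # exons 1 (coding 120) and 2 (coding 180) fully inside: 300 % 3 == 0
  res <- affected_exons(50L, 490L, g, "deletion")
  expect_equal(res$exons, c(1L, 2L))
  expect_true(res$in_frame)
  # a single 100-nt coding exon: out of frame
  res <- affected_exons(450L, 650L, g, "deletion")
  expect_equal(res$exons, 3L)
  expect_false(res$in_frame)
  # non-deletion: overlap list, frame not applicable
  res <- affected_exons(450L, 650L, g, "inversion")
  expect_equal(res$exons, c(2L, 3L))
  expect_true(is.na(res$in_frame))
  # partial overlap does not delete an exon
  res <- affected_exons(150L, 400L, g, "deletion")
  expect_equal(res$exons, integer(0))
})

test_that("SV filters are pure and commute", {
  withr::with_seed(21, {
    svs <- do.call(rbind, lapply(1:30, function(i) {
      sv_record(sample_id = paste0("s", i %% 6),
                pos1 = sample(1e5, 1L), pos2 = sample(1e5, 1L) + 2e5,
                unique_reads = sample(0:12, 1L),
                junction_fraction = round(runif(1), 2),
                variant_read_pairs = sample(0:8, 1L))
    }))
    a <- filter_sv_tcga(filter_sv_support(svs))
    b <- filter_sv_support(filter_sv_tcga(svs))
    expect_equal(as.data.frame(a), as.data.frame(b))
  })
})

test_that("planted rearrangements survive the filters, decoys do not", {
  b <- simulate_paired_cohort(simulation_config(seed = 31))
  kept <- filter_sv_recurrent(filter_sv_support(b$svs), b$svs,
                              n_samples = nrow(b$samples))
  expect_equal(sort(unique(kept$class)),
               c("planted_deletion", "planted_inversion"))
  ann <- annotate_intragenic(kept)
  expect_equal(ann$event_class[ann$class == "planted_deletion"], "deletion")
  expect_equal(ann$event_class[ann$class == "planted_inversion"],
               "inversion")
  expect_equal(ann$gene_id, c("CNTNAP2", "CNTNAP2"))
  # the planted deletion removes a contiguous in-frame exon block
  del <- ann[ann$event_class == "deletion", ]
  ae <- affected_exons(del$pos1, del$pos2, gene_model("CNTNAP2"),
                       "deletion")
  expect_equal(ae$exons, 2:8)
  expect_true(ae$in_frame)
})

test_that("headered BEDPE round-trips the evidence columns", {
  svs <- rbind(sv_record(), sv_record(pos1 = 7000L, strand1 = "-",
                                      junction_fraction = NA))
  svs$sv_id <- c("sv0001", "sv0002")
  path <- withr::local_tempfile(fileext = ".bedpe")
  write_bedpe(svs, path)
  back <- read_bedpe(path)
  expect_equal(back$pos1, svs$pos1)
  expect_equal(back$strand1, svs$strand1)
  expect_equal(back$junction_fraction, svs$junction_fraction)
  expect_equal(back$variant_read_pairs, svs$variant_read_pairs)
})
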