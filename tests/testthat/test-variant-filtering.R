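test_that("support filter applies inclusive read and VAF thresholds", {
  calls <- rbind(
    call_row(pos = 1L, alt_reads = 2L, ref_reads = 2L),    # vaf 0.5, support 2
    call_row(pos = 2L, alt_reads = 3L, ref_reads = 27L),   # vaf exactly 0.10
    call_row(pos = 3L, alt_reads = 0L, ref_reads = 50L),   # no support
    call_row(pos = 4L, alt_reads = 30L, ref_reads = 10L))  # clearly retained
  kept <- filter_by_support(calls)
  expect_equal(kept$pos, c(2L, 4L))
  expect_equal(nrow(filter_by_support(calls[0, ])), 0L)
  # order preserved
  expect_equal(kept$pos, sort(kept$pos))
})

test_that("artifact chi-square matches the Pearson 2xP contingency test", {
  # identical fractions: statistic exactly 0 regardless of patient count
  for (p_n in c(2L, 5L, 8L)) {
    counts <- data.frame(patient_id = paste0("p", seq_len(p_n)),
                         alt_sum = 10L, total_sum = 100L)
    res <- artifact_chisq(counts)
    expect_equal(res$statistic, 0)
    expect_equal(res$p_value, 1)
    expect_equal(res$df, p_n - 1L)
  }
  # hand-derivable case: (40/50) vs (0/50) -> 200/3 with df 1
  res <- artifact_chisq(data.frame(patient_id = c("p1", "p2"),
                                   alt_sum = c(40L, 0L),
                                   total_sum = c(50L, 50L)))
  expect_equal(res$statistic, 200 / 3)
  expect_equal(res$df, 1L)
  # degenerate pooled fractions
  res0 <- artifact_chisq(data.frame(patient_id = c("p1", "p2"),
                                    alt_sum = c(0L, 0L),
                                    total_sum = c(50L, 60L)))
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p_value, 1)
  res1 <- artifact_chisq(data.frame(patient_id = c("p1", "p2"),
                                    alt_sum = c(50L, 60L),
                                    total_sum = c(50L, 60L)))
  expect_equal(res1$p_value, 1)
  # a zero-total patient is excluded; too few usable patients is an error
  res <- artifact_chisq(data.frame(patient_id = c("p1", "p2", "p3"),
                                   alt_sum = c(10L, 20L, 0L),
                                   total_sum = c(50L, 50L, 0L)))
  expect_equal(res$n_patients, 2L)
  expect_error(artifact_chisq(data.frame(patient_id = "p1", alt_sum = 5L,
                                         total_sum = 10L)),
               "fewer than 2")
})

test_that("artifact chi-square equals stats::chisq.test on random tables", {
  withr::with_seed(42, {
    for (rep in 1:200) {
      p_n <- sample(2:5, 1L)
      tot <- sample(10:200, p_n, replace = TRUE)
      alt <- vapply(tot, function(t) sample.int(t - 1L, 1L), integer(1))
      counts <- data.frame(patient_id = paste0("p", seq_len(p_n)),
                           alt_sum = alt, total_sum = tot)
      res <- artifact_chisq(counts)
      ref <- suppressWarnings(
        stats::chisq.test(rbind(alt, tot - alt), correct = FALSE))
      expect_equal(res$statistic, unname(ref$statistic), tolerance = 1e-12)
      expect_equal(res$p_value, unname(ref$p.value), tolerance = 1e-12)
      expect_equal(res$df, unname(ref$parameter))
    }
  })
})

test_that("artifact filtering removes the shared stratum, keeps private events", {
  b <- simulate_paired_cohort(simulation_config(seed = 7))
  calls <- filter_by_support(b$variants)
  kept <- filter_artifacts(calls, b$cohort_counts, alpha = 0.01)
  art_in <- sum(calls$class == "artifact")
  art_out <- sum(kept$class == "artifact")
  expect_gt(art_in, 0)
  expect_lte(art_out / art_in, 0.05)          # >= 95% of artifacts removed
  expect_gte(sum(kept$class == "somatic") / sum(calls$class == "somatic"),
             0.95)                            # private somatic events retained
  audit <- attr(kept, "audit")
  expect_true(all(c("variant", "statistic", "df", "p", "decision") %in%
                    names(audit)))
  # raising alpha never removes a previously retained call
  keys <- function(d) variant_key(d$chrom, d$pos, d$ref, d$alt)
  k1 <- keys(filter_artifacts(calls, b$cohort_counts, alpha = 0.001))
  k2 <- keys(filter_artifacts(calls, b$cohort_counts, alpha = 0.05))
  expect_true(all(k1 %in% k2))
  # a call without cohort counts is an error naming the variant
  orphan <- call_row(chrom = "chrMISSING", pos = 1L)
  expect_error(filter_artifacts(orphan, b$cohort_counts, 0.01), "chrMISSING")
})

test_that("germline exclusion is allele-exact", {
  calls <- rbind(call_row(pos = 10L, ref = "A", alt = "T"),
                 call_row(pos = 20L, ref = "C", alt = "G"))
  bl <- data.frame(chrom = "chr1", pos = 10L, ref = "A", alt = "T")
  expect_equal(filter_germline(calls, bl)$pos, 20L)
  # same position, different alt allele: retained
  bl2 <- data.frame(chrom = "chr1", pos = 10L, ref = "A", alt = "G")
  expect_equal(nrow(filter_germline(calls, bl2)), 2L)
  # empty blacklist leaves input unchanged
  expect_identical(filter_germline(calls, character(0)), calls)
})

test_that("support and germline filters commute", {
  withr::with_seed(11, {
    calls <- do.call(rbind, lapply(1:40, function(i) {
      call_row(pos = i, alt_reads = sample(0:10, 1L),
               ref_reads = sample(0:60, 1L) + 1L)
    }))
    bl <- data.frame(chrom = "chr1", pos = c(3L, 7L, 21L), ref = "A",
                     alt = "T")
    a <- filter_germline(filter_by_support(calls), bl)
    b <- filter_by_support(filter_germline(calls, bl))
    expect_equal(a, b)
  })
})

test_that("blacklist VCF round-trips and malformed lines are located", {
  sites <- data.frame(chrom = c("chr1", "chr7"), pos = c(100L, 2000L),
                      ref = c("A", "C"), alt = c("G", "T"))
  path <- withr::local_tempfile(fileext = ".vcf")
  write_site_blacklist(sites, path)
  expect_equal(read_site_blacklist(path), sites)
  writeLines(c("##fileformat=VCFv4.2", "chr1\t100\t.\tA\tG", "chr2\tbad"),
             path)
  expect_error(read_site_blacklist(path), "line 3")
})

test_that("single-sample VCF round-trips read counts", {
  calls <- rbind(call_row(pos = 5L, alt_reads = 12L, ref_reads = 30L),
                 call_row(pos = 2L, ref = "G", alt = "C", alt_reads = 4L,
                          ref_reads = 40L))
  path <- withr::local_tempfile(fileext = ".vcf")
  write_variant_vcf(calls, path)
  back <- read_variant_vcf(path)
  expect_equal(back$pos, c(2L, 5L))          # coordinate-sorted on write
  expect_equal(sum(back$alt_reads), 16L)
  expect_equal(back$sample_id, rep("s1", 2L))
})

test_that("per-patient pooling sums primary and relapse reads", {
  calls <- rbind(
    call_row(pos = 1L, sample_id = "p1_primary", patient_id = "p1",
             alt_reads = 5L, ref_reads = 20L),
    call_row(pos = 1L, sample_id = "p1_relapse", patient_id = "p1",
             timepoint = "relapse", alt_reads = 7L, ref_reads = 18L),
    call_row(pos = 1L, sample_id = "p2_primary", patient_id = "p2",
             alt_reads = 0L, ref_reads = 30L))
  cc <- cohort_variant_counts(calls)
  expect_equal(nrow(cc), 2L)
  expect_equal(cc$alt_sum[cc$patient_id == "p1"], 12L)
  expect_equal(cc$total_sum[cc$patient_id == "p1"], 50L)
  expect_equal(cc$total_sum[cc$patient_id == "p2"], 30L)
})
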