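test_that("log ratio is zero for identical tracks and scale-invariant", {
  t1 <- flat_track()
  lr <- log_ratio(t1, t1)
  expect_true(all(lr$log_ratio == 0))
  t2 <- t1; t2$count <- t2$count * 7L
  expect_equal(log_ratio(t2, t1)$log_ratio, lr$log_ratio)
})

test_that("log ratio matches direct arithmetic on a planted arm loss", {
  normal <- flat_track(count = 100L)
  tumor <- normal
  lost <- tumor$chrom == "chrA" & tumor$start < 10000L   # halve 10 windows
  tumor$count[lost] <- 50L
  lr <- log_ratio(tumor, normal)
  t_tot <- sum(tumor$count); n_tot <- sum(normal$count)
  expect_equal(lr$log_ratio[lost],
               rep(log2((50 / t_tot) / (100 / n_tot)), sum(lost)))
  # after normalization the lost windows sit near -1
  expect_equal(median(lr$log_ratio[lost]), -1, tolerance = 0.25)
})

test_that("zero counts are masked, never infinite", {
  normal <- flat_track(); tumor <- flat_track()
  normal$count[3] <- 0L
  tumor$count[5] <- 0L
  lr <- log_ratio(tumor, normal)
  expect_true(is.na(lr$log_ratio[3]))
  expect_true(is.na(lr$log_ratio[5]))
  expect_true(all(is.finite(lr$log_ratio[-c(3, 5)])))
  bad <- flat_track(n_windows = 10L, chroms = c(chrA = 10L))
  expect_error(log_ratio(tumor, bad), "windowing")
})

test_that("median decimation collapses blocks to medians", {
  track <- data.frame(chrom = "chrA", start = (0:199) * 1000L,
                      end = (1:200) * 1000L, log_ratio = as.numeric(1:200))
  expect_equal(median_decimate(track, 1L)$log_ratio, track$log_ratio)
  dec <- median_decimate(track, 200L)
  expect_equal(nrow(dec), 1L)
  expect_equal(dec$log_ratio, 100.5)
  expect_equal(dec$start, 0L)
  expect_equal(dec$end, 200000L)
  expect_error(median_decimate(track, 0L), "at least 1")
})

test_that("decimation is mask-robust and length ceil(n/factor) per chromosome", {
  withr::with_seed(9, {
    track <- data.frame(chrom = rep(c("chrA", "chrB"), c(450L, 230L)),
                        start = c((0:449) * 1000L, (0:229) * 1000L),
                        end = c((1:450) * 1000L, (1:230) * 1000L),
                        log_ratio = 0.7)
    track$log_ratio[sample(nrow(track), 68L)] <- NA    # ~10% masked
    dec <- median_decimate(track, 100L)
    expect_equal(nrow(dec), ceiling(450 / 100) + ceiling(230 / 100))
    expect_true(all(dec$log_ratio == 0.7))             # constant preserved
    # decimation is idempotent on the constant result
    dec2 <- median_decimate(dec, 100L)
    expect_true(all(dec2$log_ratio == 0.7))
    # an all-masked block stays masked
    track$log_ratio[1:100] <- NA
    expect_true(is.na(median_decimate(track, 100L)$log_ratio[1]))
  })
})

test_that("arm calls threshold the median of unmasked windows", {
  arms <- data.frame(chrom = c("chrA", "chrA", "chrB", "chrB"),
                     start = c(0L, 10000L, 0L, 10000L),
                     end = c(10000L, 20000L, 10000L, 20000L),
                     arm = c("Ap", "Aq", "Bp", "Bq"))
  track <- flat_track()
  track$log_ratio <- 0; track$count <- NULL
  ac <- arm_summary(track, arms)
  expect_true(all(ac$call == "neutral"))
  track$log_ratio[track$chrom == "chrA" & track$start < 10000L] <- -1
  track$log_ratio[track$chrom == "chrB" & track$start >= 10000L] <- 0.58
  ac <- arm_summary(track, arms)
  expect_equal(ac$call[ac$arm == "Ap"], "loss")
  expect_equal(ac$call[ac$arm == "Bq"], "gain")
  expect_equal(ac$call[ac$arm == "Aq"], "neutral")
  # an arm with no unmasked window yields a missing call
  track$log_ratio[track$chrom == "chrB" & track$start < 10000L] <- NA
  expect_true(is.na(arm_summary(track, arms)$call[3]))
})

test_that("codeletion requires loss of both 1p and 19q", {
  mk <- function(p1, q19) data.frame(arm = c("1p", "19q"),
                                     chrom = c("chr1", "chr19"),
                                     median_log_ratio = 0,
                                     call = c(p1, q19))
  expect_true(detect_codeletion(mk("loss", "loss")))
  expect_false(detect_codeletion(mk("loss", "neutral")))
  expect_false(detect_codeletion(mk("gain", "loss")))
  expect_error(detect_codeletion(mk("loss", "loss")[1, ]), "19q")
})

test_that("focal deletions are bounded runs overlapping genes", {
  genes <- data.frame(gene_id = "G", chrom = "chrA", start = 4000L,
                      end = 9000L, strand = "+", tss = 4000L)
  track <- data.frame(chrom = "chrA", start = (0:39) * 1000L,
                      end = (1:40) * 1000L, log_ratio = 0)
  expect_equal(nrow(focal_deletions(track, genes)), 0L)   # flat track
  track$log_ratio[4:8] <- -2                              # windows 3000-8000
  fd <- focal_deletions(track, genes)
  expect_equal(nrow(fd), 1L)
  expect_equal(fd$start, 3000L)
  expect_equal(fd$end, 8000L)
  expect_true(fd$tss_overlap)
  # arm-wide loss is excluded as non-focal by the span bound
  wide <- track; wide$log_ratio <- -1.5
  expect_equal(nrow(focal_deletions(wide, genes, max_span = 10000L)), 0L)
  # a run missing the TSS reports tss_overlap FALSE
  track2 <- track; track2$log_ratio <- 0; track2$log_ratio[7:8] <- -2
  expect_false(focal_deletions(track2, genes)$tss_overlap)
})

test_that("bedGraph export/import round-trips unmasked windows", {
  track <- data.frame(chrom = rep("chrA", 5L), start = (0:4) * 1000L,
                      end = (1:5) * 1000L,
                      log_ratio = c(-1, 0.5, NA, 0.25, 0))
  path <- withr::local_tempfile(fileext = ".bedGraph")
  write_bedgraph(track, path, name = "t")
  back <- read_bedgraph(path)
  expect_equal(back$start, track$start[!is.na(track$log_ratio)])
  expect_equal(back$log_ratio, track$log_ratio[!is.na(track$log_ratio)])
})

test_that("planted arm events are recovered from the simulated bundle", {
  b <- simulate_paired_cohort(simulation_config(seed = 12))
  lr <- log_ratio(b$coverage$tumor[["patient1_relapse"]],
                  b$coverage$normal)
  ac <- arm_summary(median_decimate(lr, 200L))
  expect_equal(ac$call[ac$arm == "1p"], "loss")
  expect_equal(ac$call[ac$arm == "19q"], "loss")
  expect_equal(ac$call[ac$arm == "7p"], "gain")
  expect_equal(ac$call[ac$arm == "7q"], "gain")
  expect_true(detect_codeletion(ac))
  fd <- focal_deletions(lr)
  hit <- fd[fd$gene_id == "PTPRD" & fd$tss_overlap, ]
  expect_equal(nrow(hit), 1L)
})
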