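# Shared fixtures: tiny constructed genomes, tracks and gene models built
# in code so every expected value is derivable by hand.

# two-chromosome micro-genome with known trinucleotides at fixed offsets
micro_genome <- function() {
  g <- Biostrings::DNAStringSet(c(
    chrA = "GACATGTCCGTTTAA",   # pos 3 = C in ACA; pos 6 = G in TGT
    chrB = "TTCGAAACTCTGGGA"))  # pos 3 = C in TCG; pos 10 = C in TCT
  g
}

# constant-count coverage track over a toy two-chromosome layout
flat_track <- function(count = 100L, n_windows = 40L, window = 1000L,
                       chroms = c(chrA = 20L, chrB = 20L)) {
  out <- do.call(rbind, lapply(names(chroms), function(ch) {
    starts <- (seq_len(chroms[[ch]]) - 1L) * window
    data.frame(chrom = ch, start = starts, end = starts + window,
               count = count, stringsAsFactors = FALSE)
  }))
  out
}

# a minimal gene model for exon arithmetic
micro_gene <- function(strand = "+") {
  ex <- data.frame(gene_id = "G", exon = 1:4,
                   start = c(100L, 300L, 500L, 700L),
                   end   = c(220L, 480L, 600L, 800L),
                   coding = c(120L, 180L, 100L, 99L),
                   stringsAsFactors = FALSE)
  if (strand == "-") { ex$start <- rev(ex$start); ex$end <- rev(ex$end) }
  list(gene_id = "G", chrom = "chrA", strand = strand, start = 50L,
       end = 900L, tss = if (strand == "+") 50L else 900L, exons = ex)
}

# one-row SV record builder
sv_record <- function(sample_id = "s1", chrom1 = "chr1", pos1 = 1000L,
                      strand1 = "+", chrom2 = "chr1", pos2 = 5000L,
                      strand2 = "-", unique_reads = 10L,
                      junction_fraction = 0.3, variant_read_pairs = 5L) {
  data.frame(sample_id = sample_id, chrom1 = chrom1, pos1 = pos1,
             strand1 = strand1, chrom2 = chrom2, pos2 = pos2,
             strand2 = strand2, unique_reads = unique_reads,
             junction_fraction = junction_fraction,
             variant_read_pairs = variant_read_pairs,
             stringsAsFactors = FALSE)
}

# variant-call row builder
call_row <- function(chrom = "chr1", pos = 100L, ref = "A", alt = "T",
                     sample_id = "s1", patient_id = "p1",
                     timepoint = "primary", alt_reads = 10L,
                     ref_reads = 10L) {
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
             sample_id = sample_id, patient_id = patient_id,
             timepoint = timepoint, alt_reads = alt_reads,
             ref_reads = ref_reads,
             vaf = alt_reads / (alt_reads + ref_reads),
             stringsAsFactors = FALSE)
}

# exact two-sided rank-sum p by full enumeration over group assignments
# (tie-free inputs); the null rank-sum distribution is symmetric, so
# tail-doubling and |W - mu| tail mass agree
wilcoxon_enum_p <- function(x, y) {
  m <- length(x); n <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(m)])
  idx <- utils::combn(m + n, m)
  w_all <- apply(idx, 2L, function(i) sum(r[i]))
  mu <- m * (m + n + 1) / 2
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}

# two-sided Fisher p by explicit enumeration of all tables with the
# observed margins (probability-mass rule)
fisher_enum_p <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  m1 <- a + b; m2 <- c_ + d; n1 <- a + c_
  ks <- max(0, n1 - m2):min(n1, m1)
  pr <- vapply(ks, function(k) {
    choose(m1, k) * choose(m2, n1 - k) / choose(m1 + m2, n1)
  }, numeric(1))
  p_obs <- pr[ks == a]
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}
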