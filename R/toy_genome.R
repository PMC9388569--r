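# A small deterministic reference genome, arm table and gene models.
#
# Every simulated dataset lives on this ~9 Mb four-chromosome genome so that
# trinucleotide contexts, arm-level copy-number calls and intragenic
# rearrangements are all computable without downloading a real assembly.
# The sequence is generated once from a fixed internal seed (independent of
# the caller's RNG state) and cached for the session; `write_toy_genome()`
# exports it as FASTA for external tools.

.toy_env <- new.env(parent = emptyenv())

# fixed internal seed for the genome sequence itself; the genome is part of
# the package's fixed study conditions, not a per-run random quantity
.TOY_GENOME_SEED <- 104729L

#' Chromosome lengths of the toy genome
#'
#' @return named integer vector of chromosome lengths (bp).
#' @export
toy_chromosomes <- function() {
  c(chr1 = 3000000L, chr7 = 2400000L, chr10 = 2000000L, chr19 = 1600000L)
}

#' The toy reference genome
#'
#' Four chromosomes (chr1, chr7, chr10, chr19; ~9 Mb total) of uniform random
#' sequence, deterministic across sessions and independent of the caller's
#' RNG. The arms of chr1/chr19 carry the planted codeletion in the default
#' simulation, chr7 the planted gain, and chr10 hosts the two focal-event
#' genes so that arm-level and focal signals never overlap.
#'
#' @return a [Biostrings::DNAStringSet] with one entry per chromosome.
#' @export
toy_genome <- function() {
  if (!is.null(.toy_env$genome)) return(.toy_env$genome)
  lens <- toy_chromosomes()
  seqs <- with_seed(.TOY_GENOME_SEED, {
    vapply(lens, function(n) {
      paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
    }, character(1))
  })
  genome <- Biostrings::DNAStringSet(seqs)
  names(genome) <- names(lens)
  .toy_env$genome <- genome
  genome
}

#' Write the toy genome as FASTA
#'
#' @param path output FASTA path.
#' @export
write_toy_genome <- function(path) {
  Biostrings::writeXStringSet(toy_genome(), path)
  invisible(path)
}

#' Chromosome-arm definitions for the toy genome
#'
#' @return BED-style data frame with columns `chrom`, `start`, `end`, `arm`
#'   (0-based half-open spans).
#' @export
toy_arms <- function() {
  lens <- toy_chromosomes()
  mid <- lens %/% 2L
  data.frame(
    chrom = rep(names(lens), each = 2L),
    start = as.integer(rbind(0L, mid)),
    end   = as.integer(rbind(mid, lens)),
    arm   = paste0(sub("chr", "", rep(names(lens), each = 2L)),
                   rep(c("p", "q"), length(lens))),
    stringsAsFactors = FALSE
  )
}

#' Gene models on the toy genome
#'
#' `PTPRD` and `CNTNAP2` (the two focal-event genes of the default
#' simulation) sit on chr10, whose arms carry no planted arm-level event;
#' six further genes provide substrate for the cohort expression/methylation
#' tables and intergenic space for decoy rearrangements.
#'
#' @return data frame with columns `gene_id`, `chrom`, `start`, `end`
#'   (0-based half-open), `strand`, `tss`.
#' @seealso [toy_exons()] for the exon structures.
#' @export
toy_genes <- function() {
  data.frame(
    gene_id = c("PTPRD", "CNTNAP2", "GENE03", "GENE04", "GENE05",
                "GENE06", "GENE07", "GENE08"),
    chrom   = c("chr10", "chr10", "chr1", "chr1", "chr7",
                "chr19", "chr19", "chr7"),
    start   = c(200000L, 1200000L, 1600000L, 2200000L, 300000L,
                100000L, 400000L, 1900000L),
    end     = c(600000L, 1700000L, 1700000L, 2300000L, 400000L,
                200000L, 500000L, 2000000L),
    strand  = c("+", "+", "+", "-", "+", "+", "-", "+"),
    tss     = c(200000L, 1200000L, 1600000L, 2300000L, 300000L,
                100000L, 500000L, 1900000L),
    stringsAsFactors = FALSE
  )
}

#' Exon structures for the toy genes
#'
#' Exons are ordered 5' to 3' in transcript order (descending coordinates on
#' minus-strand genes); `coding` is the coding length contributed by each
#' exon, used for the in-frame test on intragenic deletions. CNTNAP2 carries
#' twelve exons whose coding lengths are all multiples of three, mirroring a
#' gene in which multi-exon deletions stay in frame.
#'
#' @return data frame with columns `gene_id`, `exon` (1-based transcript
#'   index), `start`, `end` (0-based half-open), `coding`.
#' @export
toy_exons <- function() {
  make <- function(gene_id, gstart, n, spacing, width, coding, strand = "+") {
    starts <- gstart + spacing * (seq_len(n) - 1L)
    df <- data.frame(
      gene_id = gene_id, exon = seq_len(n),
      start = as.integer(starts), end = as.integer(starts + width),
      coding = as.integer(coding), stringsAsFactors = FALSE
    )
    if (strand == "-") {             # transcript order = descending coords
      df$start <- rev(df$start); df$end <- rev(df$end)
    }
    df
  }
  rbind(
    make("PTPRD",   200000L, 10L, 40000L, 200L,
         c(151L, 120L, 133L, 150L, 98L, 162L, 141L, 150L, 120L, 200L)),
    make("CNTNAP2", 1200000L, 12L, 41000L, 200L,
         c(120L, 135L, 150L, 141L, 162L, 108L, 99L, 123L, 156L, 144L,
           117L, 150L)),
    make("GENE03", 1600000L, 4L, 20000L, 200L, 150L),
    make("GENE04", 2200000L, 4L, 20000L, 200L, 150L, strand = "-"),
    make("GENE05",  300000L, 4L, 20000L, 200L, 150L),
    make("GENE06",  100000L, 4L, 20000L, 200L, 150L),
    make("GENE07",  400000L, 4L, 20000L, 200L, 150L, strand = "-"),
    make("GENE08", 1900000L, 4L, 20000L, 200L, 150L)
  )
}

#' Assemble a single gene model
#'
#' @param gene_id gene identifier present in `genes`.
#' @param genes gene table as from [toy_genes()].
#' @param exons exon table as from [toy_exons()].
#' @return list with fields `gene_id`, `chrom`, `strand`, `start`, `end`,
#'   `tss` and an `exons` data frame in transcript order.
#' @export
gene_model <- function(gene_id, genes = toy_genes(), exons = toy_exons()) {
  g <- genes[genes$gene_id == gene_id, , drop = FALSE]
  if (nrow(g) != 1L) stopf("unknown gene '%s'", gene_id)
  list(gene_id = gene_id, chrom = g$chrom, strand = g$strand,
       start = g$start, end = g$end, tss = g$tss,
       exons = exons[exons$gene_id == gene_id, , drop = FALSE])
}
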