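# Trinucleotide-context substitution counting (96 channels, pyrimidine-
# reference convention) and POLE hypermutator scoring.

.PYRIMIDINES <- c("C", "T")
.BASES <- c("A", "C", "G", "T")

#' The 96 substitution channels
#'
#' Pyrimidine-reference trinucleotide channels in the conventional order:
#' substitution types C>A, C>G, C>T, T>A, T>C, T>G, each with the sixteen
#' 5'/3' flank combinations, formatted `5'[ref>alt]3'`.
#'
#' @return character vector of 96 channel labels.
#' @export
sbs96_channels <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  unlist(lapply(subs, function(s) {
    as.vector(t(outer(.BASES, .BASES,
                      function(a, b) paste0(a, "[", s, "]", b))))
  }))
}

# the three channels of the POLE exonuclease-deficiency signature:
# TCT>TAT, TCG>TTG, TTT>TGT
.POLE_CHANNELS <- c("T[C>A]T", "T[C>T]G", "T[T>G]T")

revcomp_base <- function(b) chartr("ACGT", "TGCA", b)

#' Trinucleotide context of a single-nucleotide substitution
#'
#' Looks up the reference trinucleotide around `pos` (1-based) and returns
#' the channel label normalized to the pyrimidine reference strand:
#' purine-reference substitutions are reverse-complemented, so a call and
#' its reverse-complement representation map to the same channel.
#'
#' @param chrom chromosome name in `reference`.
#' @param pos 1-based position; both flanking bases must exist.
#' @param ref,alt single reference/alternate bases; `ref` must match the
#'   reference sequence.
#' @param reference a [Biostrings::DNAStringSet] genome.
#' @return channel label such as `"A[C>T]A"`.
#' @export
trinucleotide_context <- function(chrom, pos, ref, alt,
                                  reference = toy_genome()) {
  if (nchar(ref) != 1L || nchar(alt) != 1L)
    stopf("only single-nucleotide substitutions have a trinucleotide context (got %s>%s)",
          ref, alt)
  if (!ref %in% .BASES || !alt %in% .BASES || ref == alt)
    stopf("invalid substitution %s>%s", ref, alt)
  if (!chrom %in% names(reference)) stopf("unknown chromosome '%s'", chrom)
  len <- length(reference[[chrom]])
  if (pos < 2L || pos > len - 1L)
    stopf("position %s:%d lacks a flanking base in the reference",
          chrom, pos)
  tri <- as.character(Biostrings::subseq(reference[[chrom]], pos - 1L,
                                         pos + 1L))
  genome_ref <- substr(tri, 2, 2)
  if (genome_ref != ref)
    stopf("reference mismatch at %s:%d: call says %s, reference has %s",
          chrom, pos, ref, genome_ref)
  if (ref %in% .PYRIMIDINES) {
    sprintf("%s[%s>%s]%s", substr(tri, 1, 1), ref, alt, substr(tri, 3, 3))
  } else {
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(tri)))
    sprintf("%s[%s>%s]%s", substr(rc, 1, 1), revcomp_base(ref),
            revcomp_base(alt), substr(rc, 3, 3))
  }
}

#' Count substitutions over the 96 trinucleotide channels
#'
#' No implicit deduplication: every input call increments its channel, so
#' `sum(counts) == total == nrow(calls)`.
#'
#' @param calls data frame of SNVs with columns `chrom`, `pos`, `ref`,
#'   `alt` (and optionally `sample_id`, recorded on the result).
#' @param reference genome as [Biostrings::DNAStringSet].
#' @return object of class `signature_counts`: list with `sample_id`,
#'   `counts` (named integer vector over [sbs96_channels()]) and `total`.
#' @export
count_channels <- function(calls, reference = toy_genome()) {
  channels <- sbs96_channels()
  counts <- stats::setNames(integer(length(channels)), channels)
  for (i in seq_len(nrow(calls))) {
    lab <- tryCatch(
      trinucleotide_context(calls$chrom[i], calls$pos[i], calls$ref[i],
                            calls$alt[i], reference),
      error = function(e) stopf("call %s:%d %s>%s: %s", calls$chrom[i],
                                calls$pos[i], calls$ref[i], calls$alt[i],
                                conditionMessage(e)))
    counts[[lab]] <- counts[[lab]] + 1L
  }
  structure(list(sample_id = if ("sample_id" %in% names(calls) &&
                                 nrow(calls)) calls$sample_id[1] else NA,
                 counts = counts, total = nrow(calls)),
            class = "signature_counts")
}

#' POLE hypermutator signature score
#'
#' Fraction of mutations in the three POLE channels (TCT>TAT, TCG>TTG,
#' TTT>TGT, i.e. `T[C>A]T`, `T[C>T]G`, `T[T>G]T`).
#'
#' @param sig a `signature_counts` object from [count_channels()].
#' @return fraction in `[0, 1]`.
#' @export
pole_signature_score <- function(sig) {
  stopifnot(inherits(sig, "signature_counts"))
  if (sig$total == 0L)
    stopf("POLE score undefined for an empty mutation set")
  sum(sig$counts[.POLE_CHANNELS]) / sig$total
}

#' Flag a POLE hypermutator sample
#'
#' True when the sample carries at least `min_mutations` mutations AND its
#' POLE signature score is at least `min_score`. The defaults (500 and 0.2)
#' separate a hypermutator relapse with on the order of a thousand
#' signature-dominated mutations from an ordinary tumor with under a
#' hundred.
#'
#' @param sig a `signature_counts` object.
#' @param min_mutations minimum mutation load.
#' @param min_score minimum POLE score.
#' @return logical flag.
#' @export
flag_hypermutator <- function(sig, min_mutations = 500L, min_score = 0.2) {
  stopifnot(inherits(sig, "signature_counts"))
  if (sig$total == 0L) return(FALSE)
  sig$total >= min_mutations && pole_signature_score(sig) >= min_score
}

#' Tabulate signature counts of several samples as a 96 x samples TSV table
#'
#' @param sigs list of `signature_counts` objects.
#' @return data frame with a `channel` column plus one column per sample.
#' @export
signature_table <- function(sigs) {
  out <- data.frame(channel = sbs96_channels(), stringsAsFactors = FALSE)
  for (s in sigs) out[[as.character(s$sample_id)]] <- as.integer(s$counts)
  out
}
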