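# Structural-variant filtering and intragenic-rearrangement annotation.
# Breakpoints are 0-based (BEDPE convention); orientations follow the
# BEDPE strand-pair reading of paired-end evidence. Gene models are
# 0-based half-open.

#' Filter structural variants by unique-read support
#'
#' @param svs SV table with an `unique_reads` column.
#' @param min_reads minimum unique supporting reads (default 5, inclusive).
#' @return retained records.
#' @export
filter_sv_support <- function(svs, min_reads = 5L) {
  svs[svs$unique_reads >= min_reads, , drop = FALSE]
}

sv_matches <- function(sv, cohort, match_window) {
  cohort$chrom1 == sv$chrom1 & cohort$chrom2 == sv$chrom2 &
    abs(cohort$pos1 - sv$pos1) <= match_window &
    abs(cohort$pos2 - sv$pos2) <= match_window &
    cohort$strand1 == sv$strand1 & cohort$strand2 == sv$strand2
}

#' Remove rearrangements recurrent across a cohort
#'
#' A record is removed iff matching rearrangements (both breakpoints within
#' `match_window`, same orientations) are present in strictly more than
#' `max_fraction` of the cohort samples — so an SV seen in exactly 30% of
#' samples survives the default filter.
#'
#' @param svs SV records to filter.
#' @param cohort SV table across the comparison cohort (with `sample_id`).
#' @param max_fraction recurrence threshold (default 0.30).
#' @param match_window breakpoint matching window in bp (default 100).
#' @param n_samples cohort size; defaults to the number of distinct
#'   `sample_id` values in `cohort`.
#' @return retained records.
#' @export
filter_sv_recurrent <- function(svs, cohort, max_fraction = 0.30,
                                match_window = 100L, n_samples = NULL) {
  if (is.null(cohort) || nrow(cohort) == 0L) return(svs)
  n_samples <- n_samples %||% length(unique(cohort$sample_id))
  keep <- vapply(seq_len(nrow(svs)), function(i) {
    m <- sv_matches(svs[i, ], cohort, match_window)
    hits <- length(unique(cohort$sample_id[m]))
    # strict "over max_fraction", guarded against binary-float artifacts
    hits <= max_fraction * n_samples + 1e-9
  }, logical(1))
  svs[keep, , drop = FALSE]
}

#' Junction-evidence filter used for cohort-level SV tables
#'
#' Retains records whose junction-spanning read fraction is at least
#' `min_fraction` OR whose variant read-pair count is at least `min_pairs`
#' (inclusive OR). Records missing both fields are rejected with a warning;
#' the number rejected is recorded in `attr(result, "rejected_missing")`.
#'
#' @param svs SV table with columns `junction_fraction` and
#'   `variant_read_pairs` (either may be `NA` per record).
#' @param min_fraction junction-fraction threshold (default 0.2).
#' @param min_pairs variant read-pair threshold (default 4).
#' @return retained records.
#' @export
filter_sv_tcga <- function(svs, min_fraction = 0.2, min_pairs = 4L) {
  jf <- svs$junction_fraction
  vp <- svs$variant_read_pairs
  missing_both <- is.na(jf) & is.na(vp)
  if (any(missing_both))
    warning(sprintf("%d SV record(s) missing both junction fraction and %s",
                    sum(missing_both), "variant read pairs; rejected"),
            call. = FALSE)
  keep <- !missing_both &
    ((!is.na(jf) & jf >= min_fraction) | (!is.na(vp) & vp >= min_pairs))
  out <- svs[keep, , drop = FALSE]
  attr(out, "rejected_missing") <- sum(missing_both)
  out
}

#' Classify a same-chromosome rearrangement from breakpoint orientations
#'
#' With breakpoints ordered so `pos1 < pos2` (orientations travel with their
#' breakpoints when swapped): `(+,-)` is a deletion, `(-,+)` a tandem
#' duplication, `(+,+)` or `(-,-)` an inversion. Interchromosomal records
#' are `other`. Classification uses breakpoint orientations only and is
#' independent of the strand of any overlapping gene.
#'
#' @param chrom1,pos1,strand1,chrom2,pos2,strand2 breakpoint fields.
#' @return one of `"deletion"`, `"duplication"`, `"inversion"`, `"other"`.
#' @export
classify_sv <- function(chrom1, pos1, strand1, chrom2, pos2, strand2) {
  if (chrom1 != chrom2) return("other")
  if (pos1 > pos2) {
    tmp <- pos1; pos1 <- pos2; pos2 <- tmp
    tmp <- strand1; strand1 <- strand2; strand2 <- tmp
  }
  key <- paste0(strand1, strand2)
  switch(key,
         "+-" = "deletion",
         "-+" = "duplication",
         "++" = , "--" = "inversion",
         "other")
}

#' Annotate intragenic rearrangements
#'
#' An SV is intragenic for a gene iff both breakpoints lie on the gene's
#' chromosome inside its span (0-based half-open). Each (record, gene) pair
#' is reported with the orientation-based event class from [classify_sv()].
#'
#' @param svs SV table.
#' @param genes gene table as from [toy_genes()].
#' @return data frame of intragenic hits: the SV columns plus `gene_id` and
#'   `event_class`.
#' @export
annotate_intragenic <- function(svs, genes = toy_genes()) {
  out <- list()
  for (i in seq_len(nrow(svs))) {
    sv <- svs[i, ]
    g <- genes[genes$chrom == sv$chrom1 & genes$chrom == sv$chrom2 &
                 genes$start <= sv$pos1 & sv$pos1 < genes$end &
                 genes$start <= sv$pos2 & sv$pos2 < genes$end, ,
               drop = FALSE]
    for (j in seq_len(nrow(g))) {
      hit <- sv
      hit$gene_id <- g$gene_id[j]
      hit$event_class <- classify_sv(sv$chrom1, sv$pos1, sv$strand1,
                                     sv$chrom2, sv$pos2, sv$strand2)
      out[[length(out) + 1L]] <- hit
    }
  }
  if (length(out) == 0L) {
    res <- svs[0, , drop = FALSE]
    res$gene_id <- character(0)
    res$event_class <- character(0)
    return(res)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Exons affected by an intragenic event
#'
#' For a deletion, lists the exons (1-based indices in transcript order)
#' fully contained in the deleted interval and reports whether the summed
#' coding length removed is divisible by three (`in_frame`). For
#' non-deletion events the overlapped exons are listed and `in_frame` is
#' `NA` (not applicable).
#'
#' @param start,end 0-based half-open interval between the breakpoints.
#' @param gene a gene model from [gene_model()].
#' @param event_class event class from [classify_sv()].
#' @return list with `exons` (integer vector of transcript-order indices)
#'   and `in_frame` (logical, `NA` for non-deletions).
#' @export
affected_exons <- function(start, end, gene, event_class = "deletion") {
  ex <- gene$exons
  if (event_class == "deletion") {
    sel <- ex$start >= start & ex$end <= end       # fully contained
    in_frame <- sum(ex$coding[sel]) %% 3L == 0L
  } else {
    sel <- ex$start < end & ex$end > start         # any overlap
    in_frame <- NA
  }
  list(exons = ex$exon[sel], in_frame = in_frame)
}

## ---- BEDPE IO --------------------------------------------------------------
# BEDPE with extra named columns (unique_reads, junction_fraction,
# variant_read_pairs) carried in a '#'-prefixed header line, the dialect
# emitted by paired-end SV callers in this workflow.

#' Write SV records as headered BEDPE
#'
#' @param svs SV table.
#' @param path output path.
#' @export
write_bedpe <- function(svs, path) {
  df <- data.frame(
    chrom1 = svs$chrom1, start1 = svs$pos1, end1 = svs$pos1 + 1L,
    chrom2 = svs$chrom2, start2 = svs$pos2, end2 = svs$pos2 + 1L,
    name = svs$sv_id %||% sprintf("sv%04d", seq_len(nrow(svs))),
    score = svs$unique_reads, strand1 = svs$strand1, strand2 = svs$strand2,
    sample_id = svs$sample_id, unique_reads = svs$unique_reads,
    junction_fraction = svs$junction_fraction,
    variant_read_pairs = svs$variant_read_pairs,
    stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(names(df), collapse = "\t")), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE, na = ".")
  invisible(path)
}

#' Read headered BEDPE written by [write_bedpe()]
#'
#' @param path input path.
#' @return SV table with the package's column names.
#' @export
read_bedpe <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L || !startsWith(lines[1], "#"))
    stopf("BEDPE file '%s' lacks the named header line", path)
  cols <- strsplit(sub("^#", "", lines[1]), "\t", fixed = TRUE)[[1]]
  body <- utils::read.table(text = lines[-1], sep = "\t", col.names = cols,
                            stringsAsFactors = FALSE, na.strings = ".")
  data.frame(sv_id = body$name, sample_id = body$sample_id,
             chrom1 = body$chrom1, pos1 = body$start1,
             strand1 = body$strand1, chrom2 = body$chrom2,
             pos2 = body$start2, strand2 = body$strand2,
             unique_reads = body$unique_reads,
             junction_fraction = body$junction_fraction,
             variant_read_pairs = body$variant_read_pairs,
             stringsAsFactors = FALSE)
}
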