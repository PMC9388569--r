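# WHO-2021 molecular subtype assignment for diffuse glioma, including the
# reclassification of lower-grade IDH-wildtype tumors with molecular
# glioblastoma features.

.WHO_LABELS <- c("oligodendroglioma_IDHmut_codel", "astrocytoma_IDHmut",
                 "glioblastoma_IDHwt", "unclassified")

#' WHO-2021 diffuse glioma subtype from molecular markers
#'
#' Assignment rule, per case:
#' \itemize{
#'   \item IDH mutant with 1p/19q codeletion: oligodendroglioma;
#'   \item IDH mutant without codeletion: IDH-mutant astrocytoma;
#'   \item IDH wildtype with grade 4, or with combined chromosome 7 gain
#'     and chromosome 10 loss, or TERT promoter mutation, or EGFR
#'     amplification: IDH-wildtype glioblastoma (this is the molecular
#'     reclassification of lower-grade IDHwt tumors);
#'   \item remaining IDH-wildtype grade 2/3 tumors: unclassified (excluded
#'     from cohort analyses).
#' }
#' Markers are tri-state (`TRUE`/`FALSE`/`NA`); an unknown marker that would
#' be decisive yields `unclassified` rather than a guess. An unknown IDH
#' status is an error, since the primary split cannot be made at all.
#'
#' @param markers data frame with columns `idh_mutant`, `codel_1p19q`,
#'   `grade`, `chr7_gain`, `chr10_loss`, `tert_promoter`,
#'   `egfr_amplified`.
#' @return character vector of subtype labels, one per row.
#' @export
classify_who2021 <- function(markers) {
  needed <- c("idh_mutant", "codel_1p19q", "grade", "chr7_gain",
              "chr10_loss", "tert_promoter", "egfr_amplified")
  miss <- setdiff(needed, names(markers))
  if (length(miss))
    stopf("marker table lacks column(s): %s", paste(miss, collapse = ", "))
  if (anyNA(markers$idh_mutant))
    stopf("IDH status unknown for %d case(s); classification requires it",
          sum(is.na(markers$idh_mutant)))
  if (!all(markers$grade %in% c(2L, 3L, 4L, NA)))
    stopf("grade must be 2, 3 or 4")
  vapply(seq_len(nrow(markers)), function(i) {
    m <- markers[i, ]
    if (m$idh_mutant) {
      if (isTRUE(m$codel_1p19q)) return("oligodendroglioma_IDHmut_codel")
      if (isFALSE(m$codel_1p19q)) return("astrocytoma_IDHmut")
      return("unclassified")                       # codeletion status unknown
    }
    gbm <- isTRUE(m$grade == 4L) ||
      (isTRUE(m$chr7_gain) && isTRUE(m$chr10_loss)) ||
      isTRUE(m$tert_promoter) || isTRUE(m$egfr_amplified)
    if (gbm) "glioblastoma_IDHwt" else "unclassified"
  }, character(1))
}

#' Tabulate subtype counts over a classified cohort
#'
#' @param labels output of [classify_who2021()].
#' @return named integer vector over the four labels (always summing to the
#'   cohort size).
#' @export
subtype_counts <- function(labels) {
  counts <- table(factor(labels, levels = .WHO_LABELS))
  stats::setNames(as.integer(counts), names(counts))
}
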