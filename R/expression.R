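# Count normalization (median-of-ratios) and paired primary/relapse
# fold-change reporting.

#' Median-of-ratios size factors
#'
#' Per sample, the median over all-positive genes of the ratio between the
#' sample's count and the gene's geometric mean across samples.
#'
#' @param counts genes x samples matrix of non-negative counts.
#' @return named vector of positive size factors.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stopf("counts must be non-negative")
  pos <- apply(counts > 0, 1L, all)
  if (!any(pos))
    stopf("no gene has positive counts in every sample; cannot normalize")
  sub <- counts[pos, , drop = FALSE]
  geo <- exp(rowMeans(log(sub)))
  apply(sub / geo, 2L, stats::median)
}

#' Paired primary/relapse normalized counts and fold change
#'
#' Normalized count is raw count divided by the sample's size factor. The
#' fold change is relapse over primary; when either normalized count is
#' zero a pseudo-count of 1 is added to both, keeping the ratio defined
#' and bounded.
#'
#' @param counts genes x samples count matrix.
#' @param gene gene (row) name.
#' @param sample_primary,sample_relapse sample (column) names.
#' @param factors optional precomputed size factors; set to 1 for inputs
#'   that are already normalized.
#' @return list with `primary`, `relapse` (normalized counts) and
#'   `fold_change`.
#' @export
paired_fold_change <- function(counts, gene, sample_primary, sample_relapse,
                               factors = NULL) {
  counts <- as.matrix(counts)
  if (!gene %in% rownames(counts)) stopf("gene '%s' not in counts", gene)
  for (s in c(sample_primary, sample_relapse))
    if (!s %in% colnames(counts)) stopf("sample '%s' not in counts", s)
  if (is.null(factors)) factors <- size_factors(counts)
  p <- counts[gene, sample_primary] / factors[[sample_primary]]
  r <- counts[gene, sample_relapse] / factors[[sample_relapse]]
  if (p == 0 || r == 0) { p <- p + 1; r <- r + 1 }
  list(primary = unname(p), relapse = unname(r), fold_change = unname(r / p))
}
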