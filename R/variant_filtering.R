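# Somatic-mutation filtering: read-support/VAF thresholds, the
# cross-patient chi-squared artifact test, and germline-database exclusion.
# Coordinates follow the 1-based VCF convention throughout.

#' Filter variant calls by read support and allele fraction
#'
#' Retains calls with at least `min_alt` unique supporting reads and a
#' variant allele fraction of `min_vaf` or higher (both boundaries
#' inclusive). Order is preserved; the input `vaf` column, if present, is
#' ignored and recomputed from the read counts.
#'
#' @param calls data frame with columns `alt_reads` and `ref_reads`.
#' @param min_alt minimum alt read count (default 3).
#' @param min_vaf minimum variant allele fraction (default 0.10).
#' @return the retained subset of `calls`.
#' @export
filter_by_support <- function(calls, min_alt = 3L, min_vaf = 0.10) {
  if (nrow(calls) == 0L) return(calls)
  if (any(calls$alt_reads < 0) || any(calls$ref_reads < 0))
    stopf("read counts must be non-negative")
  total <- calls$alt_reads + calls$ref_reads
  vaf <- ifelse(total > 0, calls$alt_reads / total, 0)
  keep <- calls$alt_reads >= min_alt & vaf >= min_vaf
  calls[keep, , drop = FALSE]
}

#' Pool per-patient allele counts for each variant
#'
#' For every variant key, sums alternate and reference reads over each
#' patient's primary and relapse samples, producing the contingency table
#' rows used by [artifact_chisq()].
#'
#' @param calls data frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `patient_id`, `alt_reads`, `ref_reads`.
#' @return data frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `patient_id`, `alt_sum`, `total_sum`.
#' @export
cohort_variant_counts <- function(calls) {
  key <- variant_key(calls$chrom, calls$pos, calls$ref, calls$alt)
  agg <- stats::aggregate(
    cbind(alt_sum = calls$alt_reads,
          total_sum = calls$alt_reads + calls$ref_reads),
    by = list(key = key, chrom = calls$chrom, pos = calls$pos,
              ref = calls$ref, alt = calls$alt,
              patient_id = calls$patient_id),
    FUN = sum)
  agg <- agg[order(agg$key, agg$patient_id), ]
  rownames(agg) <- NULL
  agg[, c("chrom", "pos", "ref", "alt", "patient_id", "alt_sum",
          "total_sum")]
}

#' Cross-patient chi-squared artifact test for one variant
#'
#' Tests the null hypothesis that every patient shares the same underlying
#' allele fraction for the variant. With pooled fraction
#' `f = sum(alt) / sum(total)`, the expected alt count per patient is
#' `f * total` and the expected ref count `(1 - f) * total`; the statistic
#' sums `(obs - exp)^2 / exp` over both cells of every patient, with
#' `patients - 1` degrees of freedom (the plain Pearson chi-square of the
#' 2 x P contingency table). Cells with zero expectation contribute zero;
#' when the pooled fraction is 0 or 1 the statistic is 0 and p is 1.
#' A low p indicates heterogeneous fractions — a genuine patient-specific
#' somatic event rather than a shared technical artifact.
#'
#' @param counts data frame with columns `patient_id`, `alt_sum`,
#'   `total_sum` (one row per patient, a single variant).
#' @return list with `statistic`, `p_value`, `df`, `n_patients`.
#' @export
artifact_chisq <- function(counts) {
  counts <- counts[counts$total_sum > 0, , drop = FALSE]
  p_n <- nrow(counts)
  if (p_n < 2L)
    stopf("artifact test undefined: fewer than 2 patients with reads")
  if (any(counts$alt_sum < 0) || any(counts$alt_sum > counts$total_sum))
    stopf("invalid counts: need 0 <= alt_sum <= total_sum")
  alt <- counts$alt_sum
  tot <- counts$total_sum
  f <- sum(alt) / sum(tot)
  df <- p_n - 1L
  if (f == 0 || f == 1)
    return(list(statistic = 0, p_value = 1, df = df, n_patients = p_n))
  exp_alt <- f * tot
  exp_ref <- (1 - f) * tot
  stat <- sum((alt - exp_alt)^2 / exp_alt) +
    sum(((tot - alt) - exp_ref)^2 / exp_ref)
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = df, lower.tail = FALSE),
       df = df, n_patients = p_n)
}

#' Remove shared-artifact variants using the cross-patient test
#'
#' Retains calls whose variant shows a statistically heterogeneous allele
#' fraction across patients (`artifact_chisq` p below `alpha`); variants
#' compatible with a single common fraction are treated as cross-cohort
#' technical artifacts and removed. The per-variant audit trail is attached
#' as `attr(result, "audit")` (variant, statistic, df, p, decision).
#'
#' @param calls variant calls to filter.
#' @param cohort_counts per-patient pooled counts from
#'   [cohort_variant_counts()] (may cover more patients than appear in
#'   `calls`, e.g. zero-alt carriers genotyped across the cohort).
#' @param alpha significance threshold (default 0.01).
#' @return retained calls, with an `audit` attribute.
#' @export
filter_artifacts <- function(calls, cohort_counts, alpha = 0.01) {
  check_fraction(alpha, "alpha", allow_zero = FALSE)
  key <- variant_key(calls$chrom, calls$pos, calls$ref, calls$alt)
  ckey <- variant_key(cohort_counts$chrom, cohort_counts$pos,
                      cohort_counts$ref, cohort_counts$alt)
  audit <- list()
  pvals <- stats::setNames(numeric(0), character(0))
  for (k in unique(key)) {
    tab <- cohort_counts[ckey == k, , drop = FALSE]
    if (nrow(tab) == 0L)
      stopf("variant %s has no cohort counts", k)
    res <- artifact_chisq(tab)
    pvals[[k]] <- res$p_value
    audit[[length(audit) + 1L]] <- data.frame(
      variant = k, statistic = res$statistic, df = res$df,
      p = res$p_value,
      decision = if (res$p_value < alpha) "retain" else "artifact",
      stringsAsFactors = FALSE)
  }
  keep <- pvals[key] < alpha
  out <- calls[keep, , drop = FALSE]
  attr(out, "audit") <- do.call(rbind, audit)
  out
}

#' Remove variants recorded in a germline database
#'
#' Allele-exact exclusion: a call is removed only when its
#' (chrom, pos, ref, alt) key appears in the blacklist.
#'
#' @param calls variant calls.
#' @param blacklist data frame with columns `chrom`, `pos`, `ref`, `alt`
#'   (e.g. from [read_site_blacklist()]), or a character vector of keys from
#'   [variant_key()].
#' @return retained calls.
#' @export
filter_germline <- function(calls, blacklist) {
  if (is.data.frame(blacklist))
    blacklist <- variant_key(blacklist$chrom, blacklist$pos, blacklist$ref,
                             blacklist$alt)
  if (length(blacklist) == 0L) return(calls)
  key <- variant_key(calls$chrom, calls$pos, calls$ref, calls$alt)
  calls[!key %in% blacklist, , drop = FALSE]
}

## ---- minimal VCF-subset IO -------------------------------------------------
# A deliberately small dialect: sites-only lines for blacklists, and single-
# sample records with an AD (alt,ref) FORMAT field for call tables. Errors
# report 1-based file line numbers.

#' Read a sites-only VCF-like blacklist
#'
#' Accepts the minimal tab-separated dialect `CHROM POS ID REF ALT ...`
#' with `##` meta lines and an optional `#CHROM` header.
#'
#' @param path file path.
#' @return data frame with columns `chrom`, `pos`, `ref`, `alt`.
#' @export
read_site_blacklist <- function(path) {
  lines <- readLines(path)
  out <- list()
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (!nzchar(ln) || startsWith(ln, "#")) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 5L)
      stopf("malformed blacklist line %d: expected at least 5 fields, got %d",
            i, length(f))
    pos <- suppressWarnings(as.integer(f[2]))
    if (is.na(pos))
      stopf("malformed blacklist line %d: position '%s' is not an integer",
            i, f[2])
    out[[length(out) + 1L]] <- data.frame(
      chrom = f[1], pos = pos, ref = f[4], alt = f[5],
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(chrom = character(), pos = integer(),
                      ref = character(), alt = character()))
  do.call(rbind, out)
}

#' Write a sites-only VCF-like blacklist
#'
#' @param sites data frame with columns `chrom`, `pos`, `ref`, `alt`.
#' @param path output path.
#' @export
write_site_blacklist <- function(sites, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(sites))
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t.",
                       sites$chrom, sites$pos, sites$ref, sites$alt), con)
  invisible(path)
}

#' Write variant calls as a minimal single-sample VCF
#'
#' One file per sample; read counts travel in the `AD` FORMAT field as
#' `alt,ref`.
#'
#' @param calls calls of a single sample.
#' @param path output path.
#' @export
write_variant_vcf <- function(calls, path) {
  stopifnot(length(unique(calls$sample_id)) <= 1L)
  sid <- if (nrow(calls)) calls$sample_id[1] else "sample"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=AD,Number=2,Type=Integer,Description=\"Alt,Ref read counts\">",
               paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
                      sid)), con)
  if (nrow(calls)) {
    o <- order(calls$chrom, calls$pos, calls$alt)
    calls <- calls[o, , drop = FALSE]
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tAD\t%d,%d",
                       calls$chrom, calls$pos, calls$ref, calls$alt,
                       calls$alt_reads, calls$ref_reads), con)
  }
  invisible(path)
}

#' Read a minimal single-sample VCF written by [write_variant_vcf()]
#'
#' @param path file path.
#' @return data frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `sample_id`, `alt_reads`, `ref_reads`, `vaf`.
#' @export
read_variant_vcf <- function(path) {
  lines <- readLines(path)
  header <- grep("^#CHROM", lines)
  if (length(header) != 1L) stopf("no #CHROM header line in '%s'", path)
  cols <- strsplit(lines[header], "\t", fixed = TRUE)[[1]]
  if (length(cols) < 10L) stopf("expected a single sample column in '%s'", path)
  sid <- cols[10]
  body <- lines[-seq_len(header)]
  body <- body[nzchar(body)]
  out <- lapply(seq_along(body), function(i) {
    f <- strsplit(body[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 10L)
      stopf("malformed VCF record at line %d of '%s'", header + i, path)
    ad <- as.integer(strsplit(f[10], ",", fixed = TRUE)[[1]])
    if (length(ad) != 2L || anyNA(ad))
      stopf("malformed AD field at line %d of '%s'", header + i, path)
    data.frame(chrom = f[1], pos = as.integer(f[2]), ref = f[4], alt = f[5],
               sample_id = sid, alt_reads = ad[1], ref_reads = ad[2],
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      sample_id = character(), alt_reads = integer(),
                      ref_reads = integer())
  res$vaf <- ifelse(res$alt_reads + res$ref_reads > 0,
                    res$alt_reads / (res$alt_reads + res$ref_reads), NA_real_)
  res
}
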