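# Small shared helpers: TSV IO with stable formatting, variant keys.

#' Write a data frame as a plain TSV
#'
#' Deterministic writer used for every tabular output so pipeline reruns are
#' byte-identical: no quoting, no row names, `NA` written as empty string.
#'
#' @param x data frame.
#' @param path output path.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "")
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#'
#' @param path input path.
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE,
                    na.strings = "", comment.char = "")
}

#' Canonical variant key
#'
#' @param chrom,pos,ref,alt vectors describing variants (1-based VCF
#'   convention).
#' @return character vector `chrom:pos:ref>alt`.
#' @export
variant_key <- function(chrom, pos, ref, alt) {
  paste0(chrom, ":", pos, ":", ref, ">", alt)
}

# run `code` with a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  withr::with_seed(seed, code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_flag <- function(x) is.logical(x) && length(x) == 1 && !is.na(x)

check_fraction <- function(x, name, allow_zero = TRUE, allow_one = TRUE) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x))
    stopf("'%s' must be a single numeric value", name)
  lo <- if (allow_zero) x >= 0 else x > 0
  hi <- if (allow_one) x <= 1 else x < 1
  if (!lo || !hi) stopf("'%s' = %g is outside its valid range", name, x)
  invisible(x)
}
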