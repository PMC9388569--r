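# Coverage-based copy number: fixed-width window counts, tumor/normal log2
# ratio tracks with library-size normalization, median decimation,
# arm-level gain/loss calls (1p/19q codeletion, chr7 gain) and focal
# TSS-deletion detection. Windows are BED-style 0-based half-open;
# terminal partial windows are kept.

#' Tile chromosomes into fixed-width windows
#'
#' @param chrom_lengths named vector of chromosome lengths.
#' @param window_size window width in bp.
#' @return data frame with columns `chrom`, `start`, `end` (0-based
#'   half-open); the last window of each chromosome may be shorter.
#' @export
make_windows <- function(chrom_lengths, window_size = 1000L) {
  if (window_size < 1L) stopf("window_size must be at least 1")
  out <- lapply(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    starts <- seq.int(0L, len - 1L, by = window_size)
    data.frame(chrom = ch, start = as.integer(starts),
               end = as.integer(pmin(starts + window_size, len)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

same_windowing <- function(a, b) {
  nrow(a) == nrow(b) && all(a$chrom == b$chrom) &&
    all(a$start == b$start) && all(a$end == b$end)
}

#' Tumor/normal coverage log ratio track
#'
#' Per window `w`: `log2((tumor_w / T) / (normal_w / N))` where `T` and `N`
#' are the genome-wide totals (library-size normalization, so scaling all
#' tumor counts by a constant leaves the track unchanged). Windows with a
#' zero normal count are masked (`NA`); windows with a zero tumor count are
#' masked as well, keeping every unmasked ratio finite.
#'
#' @param tumor,normal coverage tracks (data frames with columns `chrom`,
#'   `start`, `end`, `count`) on identical windowing.
#' @return log-ratio track: columns `chrom`, `start`, `end`, `log_ratio`.
#' @export
log_ratio <- function(tumor, normal) {
  if (!same_windowing(tumor, normal))
    stopf("tumor and normal tracks have different windowing")
  t_tot <- sum(tumor$count)
  n_tot <- sum(normal$count)
  if (t_tot <= 0 || n_tot <= 0) stopf("empty coverage track")
  lr <- log2((tumor$count / t_tot) / (normal$count / n_tot))
  lr[normal$count == 0 | tumor$count == 0] <- NA_real_
  data.frame(chrom = tumor$chrom, start = tumor$start, end = tumor$end,
             log_ratio = lr, stringsAsFactors = FALSE)
}

#' Median-decimate a log-ratio track
#'
#' Collapses consecutive non-overlapping blocks of `factor` windows per
#' chromosome to their median to suppress noise. Masked windows are
#' excluded from each block median; a block whose windows are all masked
#' stays masked. The terminal partial block uses its own median. Output
#' length per chromosome is `ceiling(n / factor)`.
#'
#' @param track log-ratio track from [log_ratio()].
#' @param factor decimation factor (default 200).
#' @return decimated log-ratio track; the applied factor is recorded in
#'   `attr(, "decimation")`.
#' @export
median_decimate <- function(track, factor = 200L) {
  if (factor < 1L) stopf("decimation factor must be at least 1")
  factor <- as.integer(factor)
  out <- lapply(split(track, factor(track$chrom, levels = unique(track$chrom))),
                function(tr) {
    n <- nrow(tr)
    block <- (seq_len(n) - 1L) %/% factor
    med <- vapply(split(tr$log_ratio, block), function(v) {
      v <- v[!is.na(v)]
      if (length(v) == 0L) NA_real_ else stats::median(v)
    }, numeric(1))
    data.frame(chrom = tr$chrom[1],
               start = vapply(split(tr$start, block), min, numeric(1)),
               end = vapply(split(tr$end, block), max, numeric(1)),
               log_ratio = unname(med), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "decimation") <- factor *
    (attr(track, "decimation") %||% 1L)
  res
}

#' Arm-level copy-number calls
#'
#' Summarizes each chromosome arm by the median of its unmasked window
#' ratios (windows assigned by start position) and calls `loss` when the
#' median is at most `loss_thr`, `gain` when at least `gain_thr`, else
#' `neutral`. An arm with no unmasked window gets an `NA` call.
#'
#' @param track log-ratio track (typically decimated).
#' @param arms arm table with columns `chrom`, `start`, `end`, `arm`.
#' @param loss_thr,gain_thr call thresholds on the median log2 ratio.
#' @return data frame with columns `arm`, `chrom`, `median_log_ratio`,
#'   `call`.
#' @export
arm_summary <- function(track, arms = toy_arms(), loss_thr = -0.3,
                        gain_thr = 0.3) {
  if (loss_thr >= gain_thr) stopf("loss_thr must be below gain_thr")
  out <- lapply(seq_len(nrow(arms)), function(i) {
    a <- arms[i, ]
    v <- track$log_ratio[track$chrom == a$chrom & track$start >= a$start &
                           track$start < a$end]
    v <- v[!is.na(v)]
    med <- if (length(v)) stats::median(v) else NA_real_
    call <- if (is.na(med)) NA_character_
      else if (med <= loss_thr) "loss"
      else if (med >= gain_thr) "gain"
      else "neutral"
    data.frame(arm = a$arm, chrom = a$chrom, median_log_ratio = med,
               call = call, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Detect the 1p/19q codeletion
#'
#' @param arm_calls output of [arm_summary()]; must contain calls for both
#'   1p and 19q.
#' @return `TRUE` iff both 1p and 19q are called `loss`.
#' @export
detect_codeletion <- function(arm_calls) {
  get <- function(a) {
    x <- arm_calls$call[arm_calls$arm == a]
    if (length(x) != 1L || is.na(x))
      stopf("codeletion status undefined: no call for arm %s", a)
    x
  }
  get("1p") == "loss" && get("19q") == "loss"
}

#' Detect focal deletions overlapping genes
#'
#' Finds maximal runs of consecutive unmasked windows with log ratio at most
#' `del_thr` whose genomic span does not exceed `max_span` (arm-scale losses
#' are thereby excluded as non-focal), and reports runs overlapping a gene
#' span. `tss_overlap` is `TRUE` when the run covers the gene's
#' transcription start site.
#'
#' @param track log-ratio track; resolution (raw or decimated) is recorded
#'   in the result.
#' @param genes gene table as from [toy_genes()].
#' @param del_thr log2-ratio threshold for deletion (default -1, a homo- or
#'   near-homozygous focal loss on top of any arm state).
#' @param max_span maximum run span in bp to count as focal (default 3 Mb).
#' @return data frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `n_windows`, `median_log_ratio`, `tss_overlap`.
#' @export
focal_deletions <- function(track, genes = toy_genes(), del_thr = -1,
                            max_span = 3e6) {
  hits <- list()
  for (ch in unique(track$chrom)) {
    tr <- track[track$chrom == ch, , drop = FALSE]
    low <- !is.na(tr$log_ratio) & tr$log_ratio <= del_thr
    r <- rle(low)
    idx_end <- cumsum(r$lengths)
    idx_start <- idx_end - r$lengths + 1L
    for (j in which(r$values)) {
      s <- tr$start[idx_start[j]]
      e <- tr$end[idx_end[j]]
      if (e - s > max_span) next
      g <- genes[genes$chrom == ch & genes$start < e & genes$end > s, ,
                 drop = FALSE]
      if (nrow(g) == 0L) next
      for (i in seq_len(nrow(g))) {
        hits[[length(hits) + 1L]] <- data.frame(
          gene_id = g$gene_id[i], chrom = ch, start = s, end = e,
          n_windows = idx_end[j] - idx_start[j] + 1L,
          median_log_ratio = stats::median(
            tr$log_ratio[idx_start[j]:idx_end[j]], na.rm = TRUE),
          tss_overlap = g$tss[i] >= s && g$tss[i] < e,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(hits) == 0L)
    return(data.frame(gene_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      n_windows = integer(), median_log_ratio = numeric(),
                      tss_overlap = logical()))
  res <- do.call(rbind, hits)
  attr(res, "resolution") <- attr(track, "decimation") %||% 1L
  res
}

## ---- bedGraph IO -----------------------------------------------------------

#' Write a track as an IGV-loadable bedGraph
#'
#' Works for coverage tracks (`count` column) and log-ratio tracks
#' (`log_ratio` column); masked windows are dropped on export, as bedGraph
#' has no missing-value representation.
#'
#' @param track coverage or log-ratio track.
#' @param path output path.
#' @param name track name for the bedGraph track line.
#' @export
write_bedgraph <- function(track, path, name = "track") {
  value <- if ("count" %in% names(track)) track$count else track$log_ratio
  keep <- !is.na(value)
  gr <- GenomicRanges::GRanges(
    seqnames = track$chrom[keep],
    ranges = IRanges::IRanges(start = track$start[keep] + 1L,
                              end = track$end[keep]),
    score = value[keep])
  rtracklayer::export.bedGraph(gr, path,
                               trackLine = methods::new(
                                 "BasicTrackLine", name = name))
  invisible(path)
}

#' Read a bedGraph file as a track data frame
#'
#' @param path bedGraph path.
#' @param value name of the value column in the result (`"count"` or
#'   `"log_ratio"`).
#' @export
read_bedgraph <- function(path, value = "log_ratio") {
  gr <- rtracklayer::import(path, format = "bedGraph")
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr) - 1L,
                    end = GenomicRanges::end(gr),
                    stringsAsFactors = FALSE)
  out[[value]] <- GenomicRanges::mcols(gr)$score
  out
}
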