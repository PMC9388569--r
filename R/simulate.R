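# Synthetic-data generator: paired primary/relapse tumor bundles and a
# TCGA-like cohort with the statistical structure the downstream analysis
# assumes (shared-artifact variant stratum, POLE hypermutator relapse,
# arm-level copy-number events, focal TSS deletion, intragenic
# rearrangements, grade-dependent expression, expression-linked survival,
# and planted methylation probe clusters).

#' Simulation configuration
#'
#' Collects and validates every parameter of the synthetic study. Defaults
#' encode the study conditions the pipeline is meant to reproduce: five
#' patients with paired primary/relapse tumors carrying 92 truncal somatic
#' SNVs each, a shared artifact stratum at a common allele fraction of 0.5,
#' one POLE hypermutator whose relapse carries 12-fold more mutations than
#' its primary with 80% of them in the three POLE channels, hemizygous 1p/19q loss plus chromosome 7 gain, a
#' focal deletion at the PTPRD transcription start site, an intragenic
#' CNTNAP2 deletion and inversion, and a 300-case cohort in which marker
#' expression falls by one log2 unit per grade and low expression carries a
#' threefold hazard.
#'
#' @param seed integer seed controlling all randomness.
#' @param n_patients number of paired-tumor patients.
#' @param n_true_somatic patient-private truncal somatic SNVs per patient.
#' @param n_artifacts cross-patient artifact variants (shared allele
#'   fraction).
#' @param artifact_vaf the common allele fraction of the artifact stratum.
#' @param depth_mean mean sequencing depth (reads per site and per 1 kb
#'   coverage window).
#' @param hypermutator_patient patient id carrying the hypermutator relapse,
#'   or `NULL` for none.
#' @param hypermutator_factor relapse/primary mutation-count ratio for the
#'   hypermutator patient.
#' @param pole_fraction fraction of the hypermutator patient's mutations
#'   drawn from the three POLE channels (TCT>TAT, TCG>TTG, TTT>TGT).
#' @param window_size coverage window width in bp.
#' @param arm_events list of `list(arm =, ratio =)` copy-ratio events applied
#'   to all tumor samples.
#' @param focal_deletions list of `list(gene =, span =, ratio =)` focal
#'   events applied to relapse samples; the deleted interval covers the
#'   gene's TSS.
#' @param sv_events list of `list(gene =, patient =, type =)` intragenic
#'   rearrangements (`"deletion"` or `"inversion"`) planted in that
#'   patient's relapse sample.
#' @param n_subthreshold per-sample decoy variants below the support/VAF
#'   thresholds.
#' @param n_germline shared germline variants, also emitted in the blacklist.
#' @param n_cohort TCGA-like cohort size.
#' @param marker_gene gene whose expression drives cohort survival.
#' @param grade_effect per-grade mean decrease of marker-gene log2
#'   expression.
#' @param hazard_ratio_low_expression hazard ratio of the low-expression
#'   group.
#' @param censoring_rate target fraction of censored cases (independent
#'   uniform censoring).
#' @param probes_per_gene methylation probes simulated per gene.
#' @param anticorrelated_cluster_size probes in the planted
#'   expression-anticorrelated cluster.
#' @param beta_noise_sd Gaussian noise sd added to methylation beta values.
#' @return validated configuration object of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_patients = 5L,
                              n_true_somatic = 92L,
                              n_artifacts = 30L,
                              artifact_vaf = 0.5,
                              depth_mean = 60,
                              hypermutator_patient = "patient2",
                              hypermutator_factor = 12,
                              pole_fraction = 0.8,
                              window_size = 1000L,
                              arm_events = list(
                                list(arm = "1p",  ratio = 0.5),
                                list(arm = "19q", ratio = 0.5),
                                list(arm = "7p",  ratio = 1.5),
                                list(arm = "7q",  ratio = 1.5)),
                              focal_deletions = list(
                                list(gene = "PTPRD", span = 50000L,
                                     ratio = 0.25)),
                              sv_events = list(
                                list(gene = "CNTNAP2", patient = "patient1",
                                     type = "deletion"),
                                list(gene = "CNTNAP2", patient = "patient2",
                                     type = "inversion")),
                              n_subthreshold = 10L,
                              n_germline = 15L,
                              n_cohort = 300L,
                              marker_gene = "CNTNAP2",
                              grade_effect = 1.0,
                              hazard_ratio_low_expression = 3,
                              censoring_rate = 0.2,
                              probes_per_gene = 10L,
                              anticorrelated_cluster_size = 5L,
                              beta_noise_sd = 0.05) {
  cfg <- list(
    seed = as.integer(seed), n_patients = as.integer(n_patients),
    n_true_somatic = as.integer(n_true_somatic),
    n_artifacts = as.integer(n_artifacts), artifact_vaf = artifact_vaf,
    depth_mean = depth_mean,
    hypermutator_patient = hypermutator_patient,
    hypermutator_factor = hypermutator_factor,
    pole_fraction = pole_fraction, window_size = as.integer(window_size),
    arm_events = arm_events, focal_deletions = focal_deletions,
    sv_events = sv_events, n_subthreshold = as.integer(n_subthreshold),
    n_germline = as.integer(n_germline), n_cohort = as.integer(n_cohort),
    marker_gene = marker_gene, grade_effect = grade_effect,
    hazard_ratio_low_expression = hazard_ratio_low_expression,
    censoring_rate = censoring_rate,
    probes_per_gene = as.integer(probes_per_gene),
    anticorrelated_cluster_size = as.integer(anticorrelated_cluster_size),
    beta_noise_sd = beta_noise_sd
  )
  check_fraction(cfg$artifact_vaf, "artifact_vaf", allow_zero = FALSE,
                 allow_one = FALSE)
  check_fraction(cfg$pole_fraction, "pole_fraction")
  check_fraction(cfg$censoring_rate, "censoring_rate", allow_one = FALSE)
  if (cfg$window_size <= 0L) stopf("'window_size' must be positive")
  if (cfg$n_patients < 1L) stopf("'n_patients' must be at least 1")
  if (cfg$depth_mean <= 0) stopf("'depth_mean' must be positive")
  if (cfg$hazard_ratio_low_expression <= 0)
    stopf("'hazard_ratio_low_expression' must be positive")
  if (cfg$anticorrelated_cluster_size >= cfg$probes_per_gene)
    stopf("'anticorrelated_cluster_size' must leave at least one probe for the independent cluster")
  genes <- toy_genes()
  for (fd in cfg$focal_deletions) {
    if (!fd$gene %in% genes$gene_id)
      stopf("focal deletion targets unknown gene '%s'", fd$gene)
    if (fd$span <= 0) stopf("focal deletion span must be positive")
  }
  arms <- toy_arms()$arm
  for (ev in cfg$arm_events) {
    if (!ev$arm %in% arms) stopf("unknown chromosome arm '%s'", ev$arm)
    if (ev$ratio <= 0) stopf("arm copy ratio must be positive")
  }
  valid_patients <- paste0("patient", seq_len(cfg$n_patients))
  if (!is.null(cfg$hypermutator_patient) &&
      !cfg$hypermutator_patient %in% valid_patients)
    stopf("hypermutator patient '%s' is not among the %d simulated patients",
          cfg$hypermutator_patient, cfg$n_patients)
  for (ev in cfg$sv_events) {
    if (!ev$gene %in% genes$gene_id)
      stopf("SV event targets unknown gene '%s'", ev$gene)
    if (!ev$type %in% c("deletion", "inversion"))
      stopf("SV event type must be 'deletion' or 'inversion', got '%s'",
            ev$type)
    if (!ev$patient %in% valid_patients)
      stopf("SV event patient '%s' is not among the simulated patients",
            ev$patient)
  }
  structure(cfg, class = "simulation_config")
}

# genome positions whose pyrimidine-strand trinucleotide matches one of the
# three POLE channels, with the corresponding genome-strand ref/alt bases;
# cached because the toy genome is fixed
pole_channel_sites <- function() {
  if (!is.null(.toy_env$pole_sites)) return(.toy_env$pole_sites)
  genome <- toy_genome()
  # pyrimidine-strand pattern and the alt base of each channel
  chan <- list(c("TCT", "A"), c("TCG", "T"), c("TTT", "G"))
  out <- list()
  for (cc in chan) {
    pat <- cc[[1]]; alt <- cc[[2]]
    rc_pat <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(pat)))
    comp <- function(b) chartr("ACGT", "TGCA", b)
    for (chromosome in names(genome)) {
      fwd <- Biostrings::start(Biostrings::matchPattern(pat,
                                                        genome[[chromosome]]))
      if (length(fwd))
        out[[length(out) + 1L]] <- data.frame(
          chrom = chromosome, pos = fwd + 1L,
          ref = substr(pat, 2, 2), alt = alt, stringsAsFactors = FALSE)
      rev <- Biostrings::start(Biostrings::matchPattern(rc_pat,
                                                        genome[[chromosome]]))
      if (length(rev))
        out[[length(out) + 1L]] <- data.frame(
          chrom = chromosome, pos = rev + 1L,
          ref = comp(substr(pat, 2, 2)), alt = comp(alt),
          stringsAsFactors = FALSE)
    }
  }
  sites <- do.call(rbind, out)
  sites <- sites[!duplicated(paste(sites$chrom, sites$pos)), ]
  .toy_env$pole_sites <- sites
  sites
}

# plain-character cache of the toy genome for vectorized base lookups
toy_genome_chars <- function() {
  if (is.null(.toy_env$genome_chars))
    .toy_env$genome_chars <- vapply(as.list(toy_genome()), as.character,
                                    character(1))
  .toy_env$genome_chars
}

# the three possible alternate bases per reference base
.ALT_TABLE <- matrix(c("C", "G", "T",  "A", "G", "T",
                       "A", "C", "T",  "A", "C", "G"),
                     nrow = 3L, dimnames = list(NULL, c("A", "C", "G", "T")))

# draw `n` random SNVs at distinct positions not in `exclude` (variant keys)
random_snvs <- function(n, exclude = character()) {
  if (n == 0L)
    return(data.frame(chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      stringsAsFactors = FALSE))
  chars <- toy_genome_chars()
  lens <- toy_chromosomes()
  out <- NULL
  while (is.null(out) || nrow(out) < n) {
    m <- n * 2L
    chrom <- sample(names(lens), m, replace = TRUE, prob = lens / sum(lens))
    # interior positions only, so every SNV has both flanking bases
    pos <- 2L + as.integer(floor(stats::runif(m) * (lens[chrom] - 2L)))
    ref <- substring(chars[chrom], pos, pos)
    alt <- .ALT_TABLE[cbind(sample.int(3L, m, replace = TRUE),
                            match(ref, colnames(.ALT_TABLE)))]
    cand <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                       stringsAsFactors = FALSE, row.names = NULL)
    key <- variant_key(cand$chrom, cand$pos, cand$ref, cand$alt)
    cand <- cand[!duplicated(key) & !key %in% exclude, , drop = FALSE]
    out <- rbind(out, cand)
    out <- out[!duplicated(variant_key(out$chrom, out$pos, out$ref,
                                       out$alt)), , drop = FALSE]
  }
  out[seq_len(n), , drop = FALSE]
}

# binomial read counts for one variant in one sample
draw_counts <- function(n, vaf, depth_mean) {
  depth <- pmax(1L, stats::rpois(n, depth_mean))
  alt <- stats::rbinom(n, depth, vaf)
  data.frame(alt_reads = alt, ref_reads = depth - alt)
}

#' Simulate a paired primary/relapse tumor cohort
#'
#' Generates per-sample somatic variant calls, tumor and matched-normal
#' coverage tracks, structural-variant tables and a germline site blacklist
#' on the toy genome. Planted truth is recorded in `class` columns so tests
#' can score recovery:
#' \itemize{
#'   \item truncal somatic SNVs private to one patient, present in both of
#'     its samples at a patient-specific VAF (uniform on 0.2--0.6);
#'   \item an artifact stratum present in every patient with counts binomial
#'     at the single common `artifact_vaf`;
#'   \item germline variants shared by all samples and listed in the
#'     blacklist;
#'   \item per-sample sub-threshold decoys (fewer than 3 supporting reads or
#'     VAF below 10%);
#'   \item a hypermutator relapse whose mutation count is
#'     `hypermutator_factor` times its primary, with `pole_fraction` of that
#'     patient's mutations drawn from POLE-channel contexts;
#'   \item coverage tracks realizing the configured arm copy ratios (all
#'     tumors) and focal TSS deletions (relapse samples);
#'   \item planted intragenic rearrangements above the support threshold plus
#'     sub-threshold decoys and a cohort-wide recurrent junction artifact.
#' }
#'
#' @param config a [simulation_config()].
#' @return list with elements `variants`, `coverage` (fields `normal`,
#'   `tumor` — a named list of tracks), `svs`, `blacklist`, `samples`, and
#'   the `config`.
#' @export
simulate_paired_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, simulate_paired_cohort_impl(config))
}

simulate_paired_cohort_impl <- function(config) {
  genome <- toy_genome()
  patients <- paste0("patient", seq_len(config$n_patients))
  samples <- data.frame(
    sample_id = as.vector(t(outer(patients, c("primary", "relapse"),
                                  paste, sep = "_"))),
    patient_id = rep(patients, each = 2L),
    timepoint = rep(c("primary", "relapse"), config$n_patients),
    stringsAsFactors = FALSE
  )

  ## ---- shared variant strata -------------------------------------------
  used <- character()
  germline <- random_snvs(config$n_germline)
  used <- c(used, variant_key(germline$chrom, germline$pos, germline$ref,
                              germline$alt))
  artifacts <- random_snvs(config$n_artifacts, exclude = used)
  used <- c(used, variant_key(artifacts$chrom, artifacts$pos, artifacts$ref,
                              artifacts$alt))

  rows <- list()
  # vectorized over variants: `vaf` recycles to nrow(vars)
  emit <- function(vars, sample_row, vaf, class) {
    if (nrow(vars) == 0L) return()
    cnt <- draw_counts(nrow(vars), rep_len(vaf, nrow(vars)),
                       config$depth_mean)
    rows[[length(rows) + 1L]] <<- data.frame(
      chrom = vars$chrom, pos = vars$pos, ref = vars$ref, alt = vars$alt,
      sample_id = sample_row$sample_id, patient_id = sample_row$patient_id,
      timepoint = sample_row$timepoint,
      alt_reads = cnt$alt_reads, ref_reads = cnt$ref_reads,
      class = class, stringsAsFactors = FALSE)
  }

  pole_pool <- pole_channel_sites()

  ## ---- per-patient somatic variants ------------------------------------
  for (p in patients) {
    hyper <- identical(p, config$hypermutator_patient)
    n_truncal <- config$n_true_somatic
    n_relapse_only <- if (hyper)
      as.integer(round(n_truncal * (config$hypermutator_factor - 1))) else 0L

    draw_somatic <- function(n) {
      if (n == 0L) return(random_snvs(0L))
      if (hyper && config$pole_fraction > 0) {
        is_pole <- stats::runif(n) < config$pole_fraction
        pole <- pole_pool[sample(nrow(pole_pool), sum(is_pole)), , drop = FALSE]
        rest <- random_snvs(n - sum(is_pole), exclude = used)
        v <- rbind(pole[, c("chrom", "pos", "ref", "alt")], rest)
      } else {
        v <- random_snvs(n, exclude = used)
      }
      v <- v[!duplicated(variant_key(v$chrom, v$pos, v$ref, v$alt)), ,
             drop = FALSE]
      used <<- c(used, variant_key(v$chrom, v$pos, v$ref, v$alt))
      v
    }

    truncal <- draw_somatic(n_truncal)
    truncal_vaf <- stats::runif(nrow(truncal), 0.2, 0.6)
    relapse_only <- draw_somatic(n_relapse_only)
    relapse_vaf <- stats::runif(nrow(relapse_only), 0.2, 0.6)

    for (tp in c("primary", "relapse")) {
      srow <- samples[samples$patient_id == p & samples$timepoint == tp, ]
      emit(truncal, srow, truncal_vaf, "somatic")
      if (tp == "relapse")
        emit(relapse_only, srow, relapse_vaf, "somatic")
      emit(artifacts, srow, config$artifact_vaf, "artifact")
      emit(germline, srow, 0.5, "germline")
      # sub-threshold decoys: half with 1-2 supporting reads, half at
      # VAF ~ 0.05 (below the 10% threshold at adequate support)
      dec <- random_snvs(config$n_subthreshold, exclude = used)
      half <- config$n_subthreshold %/% 2L
      if (half > 0L) {
        depth <- pmax(10L, stats::rpois(half, config$depth_mean))
        alt <- sample(1:2, half, replace = TRUE)
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = dec$chrom[seq_len(half)], pos = dec$pos[seq_len(half)],
          ref = dec$ref[seq_len(half)], alt = dec$alt[seq_len(half)],
          sample_id = srow$sample_id, patient_id = srow$patient_id,
          timepoint = srow$timepoint, alt_reads = alt,
          ref_reads = depth - alt, class = "subthreshold",
          stringsAsFactors = FALSE)
      }
      if (nrow(dec) > half) {
        # low-VAF decoys: counts pinned at ~5% so they always sit below
        # the 10% VAF threshold
        n2 <- nrow(dec) - half
        depth2 <- pmax(20L, stats::rpois(n2, config$depth_mean))
        alt2 <- pmax(1L, as.integer(round(0.05 * depth2)))
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = dec$chrom[(half + 1L):nrow(dec)],
          pos = dec$pos[(half + 1L):nrow(dec)],
          ref = dec$ref[(half + 1L):nrow(dec)],
          alt = dec$alt[(half + 1L):nrow(dec)],
          sample_id = srow$sample_id, patient_id = srow$patient_id,
          timepoint = srow$timepoint, alt_reads = alt2,
          ref_reads = depth2 - alt2, class = "subthreshold",
          stringsAsFactors = FALSE)
      }
    }
  }

  variants <- do.call(rbind, rows)
  variants$vaf <- variants$alt_reads /
    (variants$alt_reads + variants$ref_reads)
  rownames(variants) <- NULL

  ## ---- coverage tracks --------------------------------------------------
  windows <- make_windows(toy_chromosomes(), config$window_size)
  nwin <- nrow(windows)
  normal <- windows
  normal$count <- stats::rpois(nwin, config$depth_mean)

  arms <- toy_arms()
  genes <- toy_genes()
  base_ratio <- rep(1, nwin)
  for (ev in config$arm_events) {
    a <- arms[arms$arm == ev$arm, ]
    hit <- windows$chrom == a$chrom & windows$start >= a$start &
      windows$start < a$end
    base_ratio[hit] <- ev$ratio
  }

  tumor <- list()
  for (k in seq_len(nrow(samples))) {
    ratio <- base_ratio
    if (samples$timepoint[k] == "relapse") {
      for (fd in config$focal_deletions) {
        g <- genes[genes$gene_id == fd$gene, ]
        del_start <- max(0L, g$tss - as.integer(0.2 * fd$span))
        del_end <- del_start + fd$span
        hit <- windows$chrom == g$chrom & windows$start >= del_start &
          windows$start < del_end
        ratio[hit] <- ratio[hit] * (fd$ratio %||% 0.25)
      }
    }
    trk <- windows
    trk$count <- stats::rpois(nwin, config$depth_mean * ratio)
    tumor[[samples$sample_id[k]]] <- trk
  }

  ## ---- structural variants ----------------------------------------------
  svs <- simulate_svs(config, samples, genes)

  ## ---- cohort re-genotyping table ---------------------------------------
  # per-patient pooled alt/total counts for every emitted variant, including
  # zero-alt counts for patients not carrying it (what re-genotyping the
  # locus across the cohort would yield); this is the input of the
  # cross-patient artifact test
  carried <- cohort_variant_counts(variants)
  ckey <- variant_key(carried$chrom, carried$pos, carried$ref, carried$alt)
  ukeys <- unique(ckey)
  extra <- list()
  for (k in ukeys) {
    have <- carried$patient_id[ckey == k]
    absent <- setdiff(patients, have)
    if (length(absent) == 0L) next
    proto <- carried[match(k, ckey), c("chrom", "pos", "ref", "alt")]
    extra[[length(extra) + 1L]] <- data.frame(
      proto, patient_id = absent, alt_sum = 0L,
      total_sum = stats::rpois(length(absent), 2 * config$depth_mean),
      row.names = NULL, stringsAsFactors = FALSE)
  }
  cohort_counts <- rbind(
    carried[, c("chrom", "pos", "ref", "alt", "patient_id", "alt_sum",
                "total_sum")],
    do.call(rbind, extra))
  cohort_counts <- cohort_counts[order(
    variant_key(cohort_counts$chrom, cohort_counts$pos, cohort_counts$ref,
                cohort_counts$alt), cohort_counts$patient_id), ]
  rownames(cohort_counts) <- NULL

  blacklist <- germline
  list(variants = variants,
       coverage = list(normal = normal, tumor = tumor),
       svs = svs, blacklist = blacklist, cohort_counts = cohort_counts,
       samples = samples, config = config)
}

# planted intragenic events, sub-threshold decoys, and a recurrent junction
# artifact shared by the whole cohort
simulate_svs <- function(config, samples, genes) {
  exons <- toy_exons()
  rows <- list()
  add <- function(sample_id, c1, p1, s1, c2, p2, s2, ur, jf, vp, class) {
    rows[[length(rows) + 1L]] <<- data.frame(
      sample_id = sample_id, chrom1 = c1, pos1 = as.integer(p1),
      strand1 = s1, chrom2 = c2, pos2 = as.integer(p2), strand2 = s2,
      unique_reads = as.integer(ur), junction_fraction = jf,
      variant_read_pairs = as.integer(vp), class = class,
      stringsAsFactors = FALSE)
  }

  for (ev in config$sv_events) {
    g <- genes[genes$gene_id == ev$gene, ]
    ex <- exons[exons$gene_id == ev$gene, ]
    sid <- paste0(ev$patient, "_relapse")
    if (ev$type == "deletion") {
      # remove exons 2..8 (or all-but-first/last for short genes)
      lo <- min(2L, nrow(ex)); hi <- min(8L, nrow(ex) - 1L)
      span <- range(c(ex$start[lo:hi], ex$end[lo:hi]))
      add(sid, g$chrom, span[1] - 500L, "+", g$chrom, span[2] + 500L, "-",
          sample(8:20, 1L), stats::runif(1, 0.25, 0.5), sample(5:12, 1L),
          "planted_deletion")
    } else {
      # intronic inversion in the 3' half of the gene
      mid <- g$start + (g$end - g$start) %/% 2L
      add(sid, g$chrom, mid + 20000L, "+", g$chrom, g$end - 15000L, "+",
          sample(8:20, 1L), stats::runif(1, 0.25, 0.5), sample(5:12, 1L),
          "planted_inversion")
    }
  }

  # recurrent junction artifact: present in every sample, above the support
  # threshold, removed only by the cohort-recurrence filter
  for (k in seq_len(nrow(samples))) {
    jit <- sample(-20:20, 2L, replace = TRUE)
    add(samples$sample_id[k], "chr1", 2500000L + jit[1], "+",
        "chr1", 2800000L + jit[2], "-",
        sample(6:15, 1L), stats::runif(1, 0.25, 0.45), sample(4:9, 1L),
        "recurrent")
  }

  # per-sample decoys below the unique-read support threshold
  for (k in seq_len(nrow(samples))) {
    for (j in 1:3) {
      p1 <- sample(100000:1400000, 1L)
      add(samples$sample_id[k], "chr1", p1, sample(c("+", "-"), 1L),
          "chr1", p1 + sample(50000:200000, 1L), sample(c("+", "-"), 1L),
          sample(1:4, 1L), stats::runif(1, 0, 0.15), sample(0:3, 1L),
          "decoy_support")
    }
  }

  out <- do.call(rbind, rows)
  out$sv_id <- sprintf("sv%04d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out[, c("sv_id", "sample_id", "chrom1", "pos1", "strand1", "chrom2",
          "pos2", "strand2", "unique_reads", "junction_fraction",
          "variant_read_pairs", "class")]
}

# solve for the uniform-censoring upper bound b giving the target expected
# censoring fraction under exponential event times
censoring_bound <- function(rates, target) {
  if (target <= 0) return(Inf)
  # P(censored | rate, b) with C ~ U(0, b):  (1 - exp(-rate*b)) / (rate*b)
  f <- function(b) mean((1 - exp(-rates * b)) / (rates * b)) - target
  stats::uniroot(f, lower = 1e-6, upper = 1e7, tol = 1e-9)$root
}

#' Simulate TCGA-like cohort tables
#'
#' Builds a diffuse-glioma-like cohort: a log2 expression matrix in which the
#' marker genes (CNTNAP2, PTPRD) decrease by `grade_effect` per grade, a
#' clinical table with the molecular markers needed for WHO-2021
#' classification and exponential survival times in which the
#' low-marker-expression group carries `hazard_ratio_low_expression` (with
#' independent uniform censoring calibrated to `censoring_rate`), and a
#' methylation beta matrix in which each gene has one planted probe cluster
#' anticorrelated with its expression and one coherent cluster driven by a
#' latent factor independent of expression.
#'
#' @param config a [simulation_config()]; `n_cohort` must be at least 10.
#' @return list with elements `expression` (genes x samples log2 matrix),
#'   `methylation` (probes x samples beta matrix), `probe_map` (probe,
#'   gene, planted-cluster label), `clinical` (markers, grade, survival) and
#'   `config`.
#' @export
simulate_tcga_like_tables <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  if (config$n_cohort < 10L)
    stopf("n_cohort = %d is too small for rank statistics (minimum 10)",
          config$n_cohort)
  with_seed(config$seed + 1L, simulate_tcga_like_tables_impl(config))
}

simulate_tcga_like_tables_impl <- function(config) {
  n <- config$n_cohort
  case_id <- sprintf("TCGA%04d", seq_len(n))

  ## ---- subtypes, grades, WHO markers ------------------------------------
  subtype <- sample(c("oligodendroglioma_IDHmut_codel", "astrocytoma_IDHmut",
                      "glioblastoma_IDHwt"), n, replace = TRUE,
                    prob = c(151, 227, 203) / 581)
  grade <- integer(n)
  grade[subtype == "oligodendroglioma_IDHmut_codel"] <-
    sample(2:3, sum(subtype == "oligodendroglioma_IDHmut_codel"),
           replace = TRUE)
  grade[subtype == "astrocytoma_IDHmut"] <-
    sample(2:4, sum(subtype == "astrocytoma_IDHmut"), replace = TRUE,
           prob = c(0.4, 0.4, 0.2))
  ngbm <- sum(subtype == "glioblastoma_IDHwt")
  # most IDHwt GBMs are grade 4; the remainder are lower-grade tumors that
  # the WHO-2021 molecular rule reclassifies as glioblastoma
  grade[subtype == "glioblastoma_IDHwt"] <-
    sample(c(4L, 2L, 3L), ngbm, replace = TRUE, prob = c(0.85, 0.07, 0.08))

  idh <- subtype != "glioblastoma_IDHwt"
  codel <- subtype == "oligodendroglioma_IDHmut_codel"
  chr7_gain <- chr10_loss <- tert <- egfr <- logical(n)
  gbm <- which(subtype == "glioblastoma_IDHwt")
  chr7_gain[gbm] <- stats::runif(length(gbm)) < 0.7
  chr10_loss[gbm] <- chr7_gain[gbm] & (stats::runif(length(gbm)) < 0.9)
  tert[gbm] <- stats::runif(length(gbm)) < 0.7
  egfr[gbm] <- stats::runif(length(gbm)) < 0.4
  # lower-grade IDHwt glioblastomas need a molecular criterion by definition
  need <- gbm[grade[gbm] < 4L & !((chr7_gain[gbm] & chr10_loss[gbm]) |
                                    tert[gbm] | egfr[gbm])]
  tert[need] <- TRUE
  tert[codel] <- stats::runif(sum(codel)) < 0.9  # common in oligodendroglioma

  ## ---- expression -------------------------------------------------------
  genes <- toy_genes()$gene_id
  base <- stats::setNames(stats::runif(length(genes), 6, 12), genes)
  base["CNTNAP2"] <- 9.75
  base["PTPRD"] <- 11.5
  expr <- matrix(0, nrow = length(genes), ncol = n,
                 dimnames = list(genes, case_id))
  for (g in genes) {
    mu <- rep(base[[g]], n)
    if (g %in% c("CNTNAP2", "PTPRD"))
      mu <- mu - config$grade_effect * (grade - 2L)
    expr[g, ] <- stats::rnorm(n, mu, 0.8)
  }

  ## ---- survival ---------------------------------------------------------
  marker <- expr[config$marker_gene, ]
  low <- marker < mean(marker)
  base_rate <- log(2) / 36          # median 36 months in the high group
  rate <- base_rate * config$hazard_ratio_low_expression^as.numeric(low)
  t_event <- stats::rexp(n, rate)
  b <- censoring_bound(rate, config$censoring_rate)
  if (is.finite(b)) {
    t_cens <- stats::runif(n, 0, b)
    event <- t_event <= t_cens
    time <- pmin(t_event, t_cens)
  } else {
    event <- rep(TRUE, n)
    time <- t_event
  }

  clinical <- data.frame(
    case_id = case_id, subtype_truth = subtype, grade = grade,
    idh_mutant = idh, codel_1p19q = codel, chr7_gain = chr7_gain,
    chr10_loss = chr10_loss, tert_promoter = tert, egfr_amplified = egfr,
    time_months = time, event = event, low_expr_truth = low,
    stringsAsFactors = FALSE
  )

  ## ---- methylation ------------------------------------------------------
  k_anti <- config$anticorrelated_cluster_size
  k_ind <- config$probes_per_gene - k_anti
  probe_rows <- list()
  meth <- matrix(0, nrow = length(genes) * config$probes_per_gene, ncol = n,
                 dimnames = list(NULL, case_id))
  pnames <- character(nrow(meth))
  r <- 0L
  clip01 <- function(x) pmin(1, pmax(0, x))
  for (g in genes) {
    z <- rank(expr[g, ]) / (n + 1)          # monotone transform of expression
    w <- stats::runif(n)                    # latent factor, independent of z
    for (i in seq_len(k_anti)) {
      r <- r + 1L
      pnames[r] <- sprintf("%s_p%02d", g, i)
      lev <- stats::runif(1, 0.75, 0.95)
      meth[r, ] <- clip01(lev - 0.6 * z +
                            stats::rnorm(n, 0, config$beta_noise_sd))
      probe_rows[[r]] <- data.frame(probe_id = pnames[r], gene_id = g,
                                    planted = "anticorrelated",
                                    stringsAsFactors = FALSE)
    }
    for (i in seq_len(k_ind)) {
      r <- r + 1L
      pnames[r] <- sprintf("%s_p%02d", g, k_anti + i)
      lev <- stats::runif(1, 0.35, 0.65)
      meth[r, ] <- clip01(lev + 0.6 * (w - 0.5) +
                            stats::rnorm(n, 0, config$beta_noise_sd))
      probe_rows[[r]] <- data.frame(probe_id = pnames[r], gene_id = g,
                                    planted = "independent",
                                    stringsAsFactors = FALSE)
    }
  }
  rownames(meth) <- pnames
  probe_map <- do.call(rbind, probe_rows)

  list(expression = expr, methylation = meth, probe_map = probe_map,
       clinical = clinical, config = config)
}
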