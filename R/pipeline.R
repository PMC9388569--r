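# End-to-end orchestration: simulate (or load) inputs, run every analysis
# stage, and write the summary artifacts (filtered call tables with audit
# trails, signature tables and hypermutator flags, arm-call and focal-
# deletion tables, annotated rearrangements, gene-level methylation,
# subtype labels, survival comparisons, an oncoprint-style summary, and a
# checksummed output manifest).

#' Pipeline configuration
#'
#' All thresholds of the workflow with their default values: 3 supporting
#' reads and 10% VAF for somatic calls, artifact-test alpha 0.01, 5 unique
#' reads and 30% cohort recurrence for rearrangements, junction fraction
#' 0.2 or 4 variant read pairs for the cohort SV table, 1000 bp coverage
#' windows with 200-fold median decimation, arm-call thresholds of +/-0.3,
#' focal-deletion threshold -1 within 3 Mb, probe variance 0.01 with 2
#' clusters and methylation cutoff 0.3, and expression cutoffs 7.8
#' (CNTNAP2) / 10.5 (PTPRD) for the fixed-cutoff survival strata. Unknown
#' keys are rejected.
#'
#' @param seed integer seed forwarded to the simulation.
#' @param sim named list of overrides for [simulation_config()].
#' @param min_alt,min_vaf somatic support filter thresholds.
#' @param alpha artifact-test significance threshold.
#' @param min_sv_reads,max_recurrent_fraction,match_window SV filters.
#' @param min_junction_fraction,min_variant_pairs cohort SV evidence filter.
#' @param decimation median-decimation factor for arm-level calling.
#' @param focal_decimation light decimation factor for focal-deletion
#'   calling (default 5, i.e. 5 kb blocks at 1 kb windows): suppresses
#'   single-window Poisson noise while keeping tens-of-kb focal events at
#'   full contrast; events shorter than one block are not detectable.
#' @param loss_thr,gain_thr arm-call thresholds.
#' @param del_thr,max_del_span focal-deletion thresholds.
#' @param min_probe_variance,meth_clusters,beta_cutoff methylation collapse.
#' @param min_mutations,min_pole_score hypermutator flag thresholds.
#' @param cutoff_cntnap2,cutoff_ptprd fixed expression cutoffs.
#' @param ... rejected; catches unknown keys.
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, sim = list(),
                            min_alt = 3L, min_vaf = 0.10, alpha = 0.01,
                            min_sv_reads = 5L, max_recurrent_fraction = 0.30,
                            match_window = 100L,
                            min_junction_fraction = 0.2,
                            min_variant_pairs = 4L,
                            decimation = 200L, focal_decimation = 5L,
                            loss_thr = -0.3,
                            gain_thr = 0.3, del_thr = -1,
                            max_del_span = 3e6,
                            min_probe_variance = 0.01, meth_clusters = 2L,
                            beta_cutoff = 0.3,
                            min_mutations = 500L, min_pole_score = 0.2,
                            cutoff_cntnap2 = 7.8, cutoff_ptprd = 10.5, ...) {
  extra <- list(...)
  if (length(extra))
    stopf("unknown configuration key(s): %s",
          paste(names(extra), collapse = ", "))
  check_fraction(min_vaf, "min_vaf")
  check_fraction(alpha, "alpha", allow_zero = FALSE, allow_one = FALSE)
  check_fraction(max_recurrent_fraction, "max_recurrent_fraction")
  check_fraction(min_junction_fraction, "min_junction_fraction")
  check_fraction(beta_cutoff, "beta_cutoff")
  check_fraction(min_pole_score, "min_pole_score")
  if (min_alt < 0 || min_sv_reads < 0 || min_variant_pairs < 0)
    stopf("read-count thresholds must be non-negative")
  if (decimation < 1 || focal_decimation < 1)
    stopf("decimation factors must be at least 1")
  if (loss_thr >= gain_thr) stopf("loss_thr must be below gain_thr")
  if (max_del_span <= 0) stopf("max_del_span must be positive")
  if (min_probe_variance < 0) stopf("min_probe_variance must be >= 0")
  if (meth_clusters < 1) stopf("meth_clusters must be at least 1")
  cfg <- as.list(environment())
  cfg$extra <- NULL
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys are [pipeline_config()] arguments.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Oncoprint-style gene x sample alteration table
#'
#' One cell per gene/sample listing its alteration classes, semicolon-
#' joined in alphabetical order; rows and columns are sorted, so identical
#' inputs give byte-identical tables. Samples with no alterations still
#' appear in the header when listed in `samples`.
#'
#' @param alterations data frame with columns `gene_id`, `sample_id`,
#'   `alteration`.
#' @param genes optional row universe; defaults to genes present.
#' @param samples optional column universe; defaults to samples present.
#' @return data frame, one row per gene, one column per sample.
#' @export
oncoprint_table <- function(alterations, genes = NULL, samples = NULL) {
  genes <- sort(unique(genes %||% alterations$gene_id))
  samples <- sort(unique(samples %||% alterations$sample_id))
  out <- data.frame(gene_id = genes, stringsAsFactors = FALSE)
  for (s in samples) {
    out[[s]] <- vapply(genes, function(g) {
      a <- alterations$alteration[alterations$gene_id == g &
                                    alterations$sample_id == s]
      paste(sort(unique(a)), collapse = ";")
    }, character(1))
  }
  out
}

#' Run the full analysis pipeline
#'
#' Simulates the paired-cohort bundle and the TCGA-like tables from the
#' configured seed, then runs every stage: somatic-variant filtering
#' (support, germline blacklist, cross-patient artifact test with audit
#' trail), mutational signatures with hypermutator flags, copy-number
#' log-ratio tracks (raw and decimated bedGraph exports, arm calls,
#' codeletion, focal deletions), rearrangement filtering and intragenic
#' annotation, methylation probe collapse, WHO-2021 classification, and
#' expression-stratified survival comparisons, writing each stage's tables
#' under `out_dir`. Deterministic given the configuration: rerunning with
#' the same seed reproduces every file byte for byte.
#'
#' On a stage failure the completed outputs are left in place and a
#' machine-readable `error_report.json` (stage, message) is written before
#' the error propagates.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory, created if needed.
#' @return manifest data frame (file, md5) for every output, invisibly
#'   also written as `manifest.tsv`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character()
  save <- function(x, name) {
    path <- file.path(out_dir, name)
    write_tsv(x, path)
    outputs <<- c(outputs, path)
    path
  }
  stage <- "setup"
  on_error <- function(e) {
    report <- list(stage = stage, message = conditionMessage(e))
    jsonlite::write_json(report, file.path(out_dir, "error_report.json"),
                         auto_unbox = TRUE)
    stopf("pipeline stage '%s' failed: %s", stage, conditionMessage(e))
  }
  tryCatch({
    stage <- "simulate"
    sim_cfg <- do.call(simulation_config,
                       c(list(seed = config$seed), config$sim))
    bundle <- simulate_paired_cohort(sim_cfg)
    cohort <- simulate_tcga_like_tables(sim_cfg)
    write_site_blacklist(bundle$blacklist,
                         file.path(out_dir, "blacklist.vcf"))
    outputs <- c(outputs, file.path(out_dir, "blacklist.vcf"))

    stage <- "variants"
    calls <- filter_by_support(bundle$variants, config$min_alt,
                               config$min_vaf)
    calls <- filter_germline(calls, bundle$blacklist)
    calls <- filter_artifacts(calls, bundle$cohort_counts, config$alpha)
    save(attr(calls, "audit"), "variant_artifact_audit.tsv")
    save(calls, "somatic_calls.tsv")

    stage <- "signature"
    sigs <- lapply(split(calls, calls$sample_id), count_channels)
    save(signature_table(sigs), "signature_counts.tsv")
    flags <- do.call(rbind, lapply(sigs, function(s) data.frame(
      sample_id = s$sample_id, total = s$total,
      pole_score = pole_signature_score(s),
      hypermutator = flag_hypermutator(s, config$min_mutations,
                                       config$min_pole_score),
      stringsAsFactors = FALSE)))
    rownames(flags) <- NULL
    save(flags, "hypermutator_flags.tsv")

    stage <- "copy_number"
    arm_rows <- list(); focal_rows <- list()
    for (sid in names(bundle$coverage$tumor)) {
      lr <- log_ratio(bundle$coverage$tumor[[sid]], bundle$coverage$normal)
      dec <- median_decimate(lr, config$decimation)
      write_bedgraph(dec, file.path(out_dir,
                                    paste0(sid, ".logratio.bedGraph")),
                     name = paste0(sid, " log2 ratio"))
      outputs <- c(outputs, file.path(out_dir,
                                      paste0(sid, ".logratio.bedGraph")))
      ac <- arm_summary(dec, toy_arms(), config$loss_thr, config$gain_thr)
      ac$sample_id <- sid
      ac$codeletion_1p19q <- detect_codeletion(ac)
      arm_rows[[sid]] <- ac
      fd <- focal_deletions(median_decimate(lr, config$focal_decimation),
                            toy_genes(), config$del_thr,
                            config$max_del_span)
      if (nrow(fd)) { fd$sample_id <- sid; focal_rows[[sid]] <- fd }
    }
    arm_calls <- do.call(rbind, arm_rows); rownames(arm_calls) <- NULL
    save(arm_calls, "arm_calls.tsv")
    focal <- if (length(focal_rows)) do.call(rbind, focal_rows) else
      data.frame(gene_id = character(), sample_id = character())
    rownames(focal) <- NULL
    save(focal, "focal_deletions.tsv")

    stage <- "rearrangements"
    svs <- filter_sv_support(bundle$svs, config$min_sv_reads)
    svs <- filter_sv_recurrent(svs, bundle$svs,
                               config$max_recurrent_fraction,
                               config$match_window,
                               n_samples = nrow(bundle$samples))
    intragenic <- annotate_intragenic(svs, toy_genes())
    if (nrow(intragenic)) {
      ann <- lapply(seq_len(nrow(intragenic)), function(i) {
        ev <- intragenic[i, ]
        ae <- affected_exons(min(ev$pos1, ev$pos2), max(ev$pos1, ev$pos2),
                             gene_model(ev$gene_id), ev$event_class)
        data.frame(exons = paste(ae$exons, collapse = ","),
                   in_frame = if (is.na(ae$in_frame)) NA else ae$in_frame)
      })
      intragenic <- cbind(intragenic, do.call(rbind, ann))
    }
    save(intragenic, "intragenic_rearrangements.tsv")

    stage <- "oncoprint"
    alt_rows <- list()
    genes <- toy_genes()
    if (nrow(focal)) {
      f <- focal[focal$tss_overlap, , drop = FALSE]
      if (nrow(f))
        alt_rows$focal <- data.frame(gene_id = f$gene_id,
                                     sample_id = f$sample_id,
                                     alteration = "focal_deletion_TSS")
    }
    if (nrow(intragenic))
      alt_rows$sv <- data.frame(gene_id = intragenic$gene_id,
                                sample_id = intragenic$sample_id,
                                alteration = paste0("intragenic_",
                                                    intragenic$event_class))
    gcall <- calls
    gidx <- vapply(seq_len(nrow(gcall)), function(i) {
      m <- which(genes$chrom == gcall$chrom[i] &
                   genes$start <= gcall$pos[i] - 1L &
                   gcall$pos[i] - 1L < genes$end)
      if (length(m)) m[1] else NA_integer_
    }, integer(1))
    hit <- !is.na(gidx)
    if (any(hit))
      alt_rows$mut <- data.frame(gene_id = genes$gene_id[gidx[hit]],
                                 sample_id = gcall$sample_id[hit],
                                 alteration = "mutation")
    alterations <- do.call(rbind, alt_rows)
    if (is.null(alterations))
      alterations <- data.frame(gene_id = character(),
                                sample_id = character(),
                                alteration = character())
    save(oncoprint_table(alterations, genes = genes$gene_id,
                         samples = bundle$samples$sample_id),
         "oncoprint.tsv")

    stage <- "methylation"
    collapsed <- collapse_gene_methylation(cohort$methylation,
                                           cohort$probe_map,
                                           cohort$expression,
                                           config$min_probe_variance,
                                           config$meth_clusters)
    gm <- data.frame(gene_id = rownames(collapsed$beta), collapsed$beta,
                     check.names = FALSE)
    save(gm, "gene_methylation.tsv")
    save(collapsed$provenance, "methylation_provenance.tsv")

    stage <- "classify"
    clin <- cohort$clinical
    clin$who2021 <- classify_who2021(clin)
    save(clin, "clinical_classified.tsv")

    stage <- "survival"
    expr <- cohort$expression
    time <- stats::setNames(clin$time_months, clin$case_id)
    event <- stats::setNames(clin$event, clin$case_id)
    comp <- list()
    for (g in c("CNTNAP2", "PTPRD")) {
      v <- expr[g, ]
      row <- survival_by_expression(v, time[names(v)], event[names(v)],
                                    "mean")
      row <- cbind(data.frame(comparison = paste0(g, "_mean_cutoff")), row)
      comp[[length(comp) + 1L]] <- row
    }
    la <- dichotomize_expression(expr["CNTNAP2", ], "fixed",
                                 config$cutoff_cntnap2)$labels
    lb <- dichotomize_expression(expr["PTPRD", ], "fixed",
                                 config$cutoff_ptprd)$labels
    combined <- combined_low_group(la, lb)
    ll <- combined == "low/low"
    if (any(ll) && !all(ll)) {
      lr <- logrank_test(time[ll], event[ll], time[!ll], event[!ll])
      comp[[length(comp) + 1L]] <- data.frame(
        comparison = "combined_lowlow", cutoff = NA_real_,
        n_low = sum(ll), n_high = sum(!ll), statistic = lr$statistic,
        p = lr$p,
        median_low = attr(km_estimate(time[ll], event[ll]), "median"),
        median_high = attr(km_estimate(time[!ll], event[!ll]), "median"))
    }
    save(do.call(rbind, comp), "survival_comparisons.tsv")

    wilc <- list()
    for (g in c("CNTNAP2", "PTPRD")) {
      for (pair in list(c(2L, 3L), c(3L, 4L), c(2L, 4L))) {
        a <- expr[g, clin$grade == pair[1]]
        b <- expr[g, clin$grade == pair[2]]
        if (length(a) && length(b)) {
          w <- wilcoxon_rank_sum(a, b)
          wilc[[length(wilc) + 1L]] <- data.frame(
            gene = g, grades = paste(pair, collapse = "v"),
            n_a = length(a), n_b = length(b),
            statistic = w$statistic, p = w$p)
        }
      }
    }
    save(do.call(rbind, wilc), "grade_wilcoxon.tsv")

    stage <- "manifest"
    manifest <- data.frame(
      file = basename(outputs),
      md5 = unname(tools::md5sum(outputs)),
      stringsAsFactors = FALSE)
    write_tsv(manifest, file.path(out_dir, "manifest.tsv"))
    manifest
  }, error = on_error)
}
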