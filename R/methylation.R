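# Probe-to-gene methylation collapse: variance filter, Spearman-distance
# average-linkage clustering, and selection of the probe cluster whose
# median beta correlates negatively with the gene's expression.

#' Variance-filter methylation probes
#'
#' Retains probes whose across-sample variance is strictly greater than
#' `min_variance` (a probe at exactly the threshold is removed).
#'
#' @param beta probes x samples matrix of beta values in `[0, 1]`.
#' @param min_variance variance threshold (default 0.01).
#' @return the retained rows of `beta`.
#' @export
filter_probes <- function(beta, min_variance = 0.01) {
  if (ncol(beta) < 2L) stopf("variance filter needs at least 2 samples")
  v <- apply(beta, 1L, stats::var)
  beta[v > min_variance, , drop = FALSE]
}

#' Spearman correlation distance between probes
#'
#' `1 - rho` with midrank (tie-corrected) Spearman correlation between probe
#' beta vectors; the diagonal is zero and perfectly anti-monotone probes are
#' at distance 2.
#'
#' @param beta probes x samples matrix (at least 2 probes, 3 samples).
#' @return symmetric probe x probe distance matrix.
#' @export
probe_distance <- function(beta) {
  if (nrow(beta) < 2L) stopf("need at least 2 probes")
  if (ncol(beta) < 3L) stopf("need at least 3 samples")
  v <- apply(beta, 1L, stats::var)
  if (any(v == 0))
    stopf("zero-variance probe(s) must be removed by filter_probes first: %s",
          paste(rownames(beta)[v == 0], collapse = ", "))
  d <- 1 - stats::cor(t(beta), method = "spearman")
  diag(d) <- 0
  d
}

#' Cluster probes by average-linkage hierarchical clustering
#'
#' Cuts the average-linkage tree on the Spearman distance into `k` clusters
#' (fewer when fewer probes exist). A single probe forms a singleton
#' cluster. Output is deterministic under a fixed input order.
#'
#' @param distance probe distance matrix from [probe_distance()], or a
#'   1-probe beta matrix.
#' @param k number of clusters to cut (default 2).
#' @return named integer vector of cluster assignments.
#' @export
cluster_probes <- function(distance, k = 2L) {
  n <- nrow(distance)
  if (n == 1L)
    return(stats::setNames(1L, rownames(distance)))
  hc <- stats::hclust(stats::as.dist(distance), method = "average")
  stats::cutree(hc, k = min(k, n))
}

#' Select the probe cluster anticorrelated with expression
#'
#' For each cluster, the per-sample median beta is correlated (Spearman)
#' with the gene's expression over the matched samples; the cluster with
#' the most negative correlation represents the gene's methylation, its
#' median-beta series becoming the gene-level value. Ties on the most
#' negative correlation are broken by larger cluster, then input order.
#' When no cluster correlates negatively the gene's methylation is flagged
#' undefined.
#'
#' @param clusters cluster assignment from [cluster_probes()].
#' @param beta probes x samples beta matrix (rows covered by `clusters`).
#' @param expression named per-sample expression vector for the gene; the
#'   sample intersection with `colnames(beta)` is used and must have at
#'   least 3 samples.
#' @return list with `defined`, `beta` (named per-sample representative
#'   beta, `NULL` when undefined), `probes`, `rho`, and `cluster_rhos`.
#' @export
select_negative_cluster <- function(clusters, beta, expression) {
  samples <- intersect(colnames(beta), names(expression))
  if (length(samples) < 3L)
    stopf("cluster selection undefined: only %d matched sample(s)",
          length(samples))
  b <- beta[names(clusters), samples, drop = FALSE]
  e <- expression[samples]
  ids <- sort(unique(clusters))
  med <- vapply(ids, function(cl) {
    apply(b[clusters == cl, , drop = FALSE], 2L, stats::median)
  }, numeric(length(samples)))
  rhos <- apply(med, 2L, function(m) {
    stats::cor(m, e, method = "spearman")
  })
  sizes <- vapply(ids, function(cl) sum(clusters == cl), integer(1))
  ord <- order(rhos, -sizes, seq_along(ids))   # most negative, then larger
  best <- ord[1]
  if (!is.finite(rhos[best]) || rhos[best] >= 0)
    return(list(defined = FALSE, beta = NULL, probes = character(),
                rho = NA_real_, cluster_rhos = rhos))
  list(defined = TRUE,
       beta = stats::setNames(med[, best], samples),
       probes = names(clusters)[clusters == ids[best]],
       rho = rhos[best], cluster_rhos = rhos)
}

#' Collapse probe-level methylation to gene level across genes
#'
#' Runs the full collapse for every gene in the probe map: variance filter,
#' Spearman-distance average-linkage clustering into `k` clusters, and
#' negative-correlation cluster selection against the gene's expression.
#'
#' @param beta probes x samples beta matrix.
#' @param probe_map data frame with columns `probe_id`, `gene_id`.
#' @param expression genes x samples expression matrix.
#' @param min_variance probe variance threshold.
#' @param k clusters to cut.
#' @return list with `beta` (genes x samples representative beta matrix,
#'   `NA` rows for undefined genes) and `provenance` (per gene: number of
#'   probes surviving the filter, chosen probes, correlation, defined
#'   flag).
#' @export
collapse_gene_methylation <- function(beta, probe_map, expression,
                                      min_variance = 0.01, k = 2L) {
  samples <- intersect(colnames(beta), colnames(expression))
  genes <- intersect(unique(probe_map$gene_id), rownames(expression))
  out <- matrix(NA_real_, nrow = length(genes), ncol = length(samples),
                dimnames = list(genes, samples))
  prov <- list()
  for (g in genes) {
    probes <- probe_map$probe_id[probe_map$gene_id == g]
    sub <- beta[rownames(beta) %in% probes, samples, drop = FALSE]
    sub <- filter_probes(sub, min_variance)
    rec <- data.frame(gene_id = g, n_probes = nrow(sub),
                      chosen_probes = "", rho = NA_real_, defined = FALSE,
                      stringsAsFactors = FALSE)
    if (nrow(sub) >= 1L) {
      cl <- if (nrow(sub) == 1L)
        stats::setNames(1L, rownames(sub))
      else cluster_probes(probe_distance(sub), k = k)
      sel <- select_negative_cluster(cl, sub, expression[g, samples])
      if (sel$defined) {
        out[g, ] <- sel$beta[samples]
        rec$chosen_probes <- paste(sel$probes, collapse = ";")
        rec$rho <- sel$rho
        rec$defined <- TRUE
      }
    }
    prov[[length(prov) + 1L]] <- rec
  }
  list(beta = out, provenance = do.call(rbind, prov))
}

#' Binary methylation status from the representative beta
#'
#' @param gene_beta per-sample representative beta values.
#' @param beta_cutoff methylation call threshold (default 0.3, inclusive).
#' @return logical per-sample methylated status.
#' @export
methylation_status <- function(gene_beta, beta_cutoff = 0.3) {
  gene_beta >= beta_cutoff
}
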