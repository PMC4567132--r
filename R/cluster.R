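#' Select probes by chromosome and CpG-island status
#'
#' The clustering substrate is the set of CpG-island probes on the
#' chromosome(s) of interest: X-linked islands for XCI inference,
#' autosomal islands for global-methylation summaries.
#'
#' @param manifest manifest `data.frame` from [read_manifest()].
#' @param chromosome_filter `"chrX"`, `"autosomal"`, or a character vector
#'   of chromosome names.
#' @param cpg_island_only keep island probes only (default `TRUE`).
#' @return probe ids in manifest order; errors if the selection is empty.
#' @export
select_probes <- function(manifest, chromosome_filter = "chrX",
                          cpg_island_only = TRUE) {
  if (identical(chromosome_filter, "autosomal")) {
    keep_chr <- manifest$chrom != "chrX"
  } else {
    keep_chr <- manifest$chrom %in% normalize_chromosome(chromosome_filter)
  }
  keep <- keep_chr & (!cpg_island_only | manifest$cpg_island)
  if (!any(keep)) {
    stop_xci("no probes match chromosome filter '%s' (cpg_island_only = %s)",
             paste(chromosome_filter, collapse = ","), cpg_island_only)
  }
  manifest$probe_id[keep]
}

#' Impute missing beta values within a stratum
#'
#' Each missing entry is replaced by the per-probe median over the
#' stratum's non-missing values. Probes with no observed value in the
#' stratum cannot be imputed and are dropped (count logged).
#'
#' @param beta probes x samples matrix (may contain `NA`).
#' @param samples sample ids defining the stratum; default all columns.
#' @return complete probes x samples matrix for the stratum.
#' @export
impute_missing <- function(beta, samples = colnames(beta)) {
  m <- beta[, samples, drop = FALSE]
  n_obs <- rowSums(!is.na(m))
  if (any(n_obs == 0)) {
    xci_log("dropped %d probe(s) with no observed value in stratum", sum(n_obs == 0))
    m <- m[n_obs > 0, , drop = FALSE]
  }
  nas <- which(is.na(m), arr.ind = TRUE)
  if (nrow(nas) > 0) {
    med <- apply(m, 1, stats::median, na.rm = TRUE)
    m[nas] <- med[nas[, 1]]
  }
  m
}

#' Complete-linkage hierarchical clustering of samples
#'
#' Samples (columns) are clustered by Euclidean distance between their
#' beta-value profiles using agglomerative clustering with complete
#' linkage, cut to exactly `k` clusters. Samples are ordered by id before
#' clustering so the result does not depend on column order; with
#' continuous beta values merge-distance ties have probability zero, and
#' in exact-tie degenerate cases the agglomeration order of the sorted
#' input breaks them deterministically.
#'
#' @param beta complete probes x samples matrix.
#' @param k number of clusters, 2 <= k <= number of samples.
#' @return named integer vector sample -> cluster label (1..k, numbered
#'   by first occurrence in sample-id order).
#' @export
cluster_samples <- function(beta, k) {
  n <- ncol(beta)
  if (k > n) stop_xci("k = %d exceeds the %d samples available", k, n)
  if (k < 1) stop_xci("k must be >= 1")
  if (anyNA(beta)) stop_xci("beta matrix must be complete; run impute_missing() first")
  ord <- order(colnames(beta))
  x <- t(beta[, ord, drop = FALSE])
  hc <- stats::hclust(stats::dist(x, method = "euclidean"), method = "complete")
  raw <- stats::cutree(hc, k = k)
  # renumber by first occurrence so labels are reproducible
  lab <- match(raw, unique(raw))
  names(lab) <- rownames(x)
  lab[colnames(beta)]
}
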