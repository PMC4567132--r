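#' Classification thresholds and chrX arm geometry
#'
#' The numeric cutoffs are calibration choices, not published values: the
#' original cluster assignments were made by visual inspection, so the
#' defaults here are calibrated on the synthetic generator. `t_hyper` and
#' `t_hypo` classify a (cluster-median or per-sample) mean X-island beta
#' as hypermethylated / hypomethylated; `t_xist` splits XIST
#' log2(RSEM + 1) into high/low; `arm_cnv_cut` is the absolute
#' length-weighted seg-mean beyond which an arm is called deleted/gained.
#'
#' @param t_hyper,t_hypo,t_xist,arm_cnv_cut numeric cutoffs.
#' @return named list of thresholds.
#' @export
xci_thresholds <- function(t_hyper = 0.35, t_hypo = 0.18, t_xist = 6.5,
                           arm_cnv_cut = 0.3) {
  if (t_hypo >= t_hyper) stop_xci("t_hypo (%.3g) must be below t_hyper (%.3g)",
                                  t_hypo, t_hyper)
  list(t_hyper = t_hyper, t_hypo = t_hypo, t_xist = t_xist,
       arm_cnv_cut = arm_cnv_cut)
}

#' @rdname xci_thresholds
#' @param centromere,chrom_length chrX geometry in bp; the p arm is
#'   `[1, centromere)`, the q arm `[centromere, chrom_length]`.
#' @export
xci_arm_def <- function(centromere = 6e7, chrom_length = 1.55e8) {
  assert_that(centromere > 0 && centromere < chrom_length,
              "centromere must fall inside the chromosome")
  list(centromere = centromere, chrom_length = chrom_length)
}

#' Characterize one methylation cluster
#'
#' A cluster's methylation class is taken from the median over members of
#' the per-sample mean X-island beta: `hyper` at or above `t_hyper`,
#' `hypo` at or below `t_hypo`, `partial` between. The XIST class is
#' `high`/`low` by the member median of log2(RSEM + 1) XIST against
#' `t_xist`, or `unknown` when more than half the members lack
#' expression data.
#'
#' @param members member sample ids.
#' @param sample_mean_beta named per-sample mean X-island beta.
#' @param xist_log named per-sample XIST log2(RSEM + 1); `NA` = missing.
#' @param thresholds from [xci_thresholds()].
#' @param cluster_id,histology labels carried into the profile.
#' @return list of class `xci_cluster_profile`.
#' @export
profile_cluster <- function(members, sample_mean_beta, xist_log,
                            thresholds = xci_thresholds(),
                            cluster_id = "C1", histology = NA_character_) {
  assert_that(length(members) > 0, "cluster '%s' has no members", cluster_id)
  mb <- sample_mean_beta[members]
  assert_that(!anyNA(mb), "missing sample mean beta for cluster '%s'", cluster_id)
  med_beta <- stats::median(mb)
  meth_class <- meth_class_of(med_beta, thresholds)
  xi <- xist_log[members]
  if (mean(is.na(xi)) > 0.5 || all(is.na(xi))) {
    xist_class <- "unknown"
  } else {
    xist_class <- if (stats::median(xi, na.rm = TRUE) >= thresholds$t_xist)
      "high" else "low"
  }
  structure(list(cluster_id = cluster_id, histology = histology,
                 member_samples = members,
                 median_sample_mean_beta = med_beta,
                 meth_class = meth_class, xist_class = xist_class),
            class = "xci_cluster_profile")
}

meth_class_of <- function(mean_beta, thresholds) {
  if (mean_beta >= thresholds$t_hyper) "hyper"
  else if (mean_beta <= thresholds$t_hypo) "hypo"
  else "partial"
}

#' Arm-level copy-number call from SEG records
#'
#' The arm's log2 seg-mean is the length-weighted mean of the segments
#' overlapping it. The arm is `deleted` at or below `-arm_cnv_cut`,
#' `gained` at or above `+arm_cnv_cut`, otherwise `neutral`. An arm with
#' less than half its length covered by segments — including samples with
#' no chrX segments at all — is called `neutral` with a logged warning:
#' absence of evidence is not evidence of loss.
#'
#' @param seg SEG `data.frame` from [read_seg()].
#' @param sample sample id.
#' @param arms from [xci_arm_def()].
#' @param thresholds from [xci_thresholds()].
#' @return named character vector `c(p = ..., q = ...)` with values in
#'   `deleted`/`neutral`/`gained`.
#' @export
call_arm_cnv <- function(seg, sample, arms = xci_arm_def(),
                         thresholds = xci_thresholds()) {
  s <- seg[seg$sample_id == sample & seg$chrom == "chrX", , drop = FALSE]
  if (nrow(s) == 0) {
    xci_log("sample '%s' has no chrX segments; both arms called neutral", sample)
    return(c(p = "neutral", q = "neutral"))
  }
  bounds <- list(p = c(1, arms$centromere - 1),
                 q = c(arms$centromere, arms$chrom_length))
  out <- c(p = "neutral", q = "neutral")
  for (arm in c("p", "q")) {
    lo <- bounds[[arm]][1]; hi <- bounds[[arm]][2]
    ov_lo <- pmax(s$start, lo); ov_hi <- pmin(s$end, hi)
    w <- pmax(ov_hi - ov_lo + 1, 0)
    arm_len <- hi - lo + 1
    if (sum(w) < 0.5 * arm_len) {
      xci_log("sample '%s' %s arm covered %.0f%% (<50%%); called neutral",
              sample, arm, 100 * sum(w) / arm_len)
      next
    }
    wm <- sum(w * s$seg_mean) / sum(w)
    out[arm] <- if (wm <= -thresholds$arm_cnv_cut) "deleted"
    else if (wm >= thresholds$arm_cnv_cut) "gained"
    else "neutral"
  }
  out
}

#' Arm-level hypomethylation call for one sample
#'
#' An arm is `hypo` when the mean beta over its CpG-island probes (at
#' least 5 required, else `no_probes`) is at or below `t_hypo`. A
#' selective event — exactly one arm hypomethylated — is the methylation
#' signature of an Xi arm deletion.
#'
#' @param betas named per-probe beta values of one sample.
#' @param manifest probe manifest.
#' @param arms from [xci_arm_def()].
#' @param t_hypo hypomethylation cutoff.
#' @return named character vector `c(p = ..., q = ...)` with values in
#'   `hypo`/`not_hypo`/`no_probes`.
#' @export
detect_arm_hypomethylation <- function(betas, manifest,
                                       arms = xci_arm_def(),
                                       t_hypo = xci_thresholds()$t_hypo) {
  x <- manifest[manifest$chrom == "chrX" & manifest$cpg_island, , drop = FALSE]
  out <- c(p = "no_probes", q = "no_probes")
  for (arm in c("p", "q")) {
    ids <- if (arm == "p") x$probe_id[x$pos < arms$centromere]
    else x$probe_id[x$pos >= arms$centromere]
    v <- betas[intersect(ids, names(betas))]
    v <- v[!is.na(v)]
    if (length(v) < 5) next
    out[arm] <- if (mean(v) <= t_hypo) "hypo" else "not_hypo"
  }
  out
}

# Pure assignment rule: the auditable core. Returns group/override/flags
# from the evidence classes alone, so stored calls can be re-derived.
assign_one <- function(meth_class, xist_class, p_cnv, q_cnv, p_meth, q_meth) {
  flags <- character(0)
  whole_x_deleted <- (p_cnv == "deleted" && q_cnv == "deleted")
  selective_p <- (p_meth == "hypo" && q_meth == "not_hypo")
  selective_q <- (q_meth == "hypo" && p_meth == "not_hypo")

  group <- switch(meth_class,
                  hyper = "preserved_Xi",
                  partial = "Xa_plus",
                  hypo = "two_Xa")
  if (meth_class == "hyper" && xist_class == "low") flags <- c(flags, "conflict_hyper_low_xist")
  if (meth_class == "hypo" && xist_class == "high") flags <- c(flags, "conflict_hypo_high_xist")
  if (meth_class %in% c("partial", "hypo") && xist_class == "unknown") {
    flags <- c(flags, "low_confidence_no_xist")
  }
  if (meth_class == "hypo" && whole_x_deleted) {
    # whole-Xi loss does not change X dosage: report as preserved-Xi
    # equivalent ("Xa-only") rather than two active X chromosomes
    group <- "preserved_Xi"
    flags <- c(flags, "whole_X_deletion_Xa_only")
  }
  override <- FALSE
  if (meth_class %in% c("partial", "hypo") &&
      ((selective_p && p_cnv == "deleted") || (selective_q && q_cnv == "deleted"))) {
    group <- "preserved_Xi"
    override <- TRUE
  }
  list(xci_group = group, override_applied = override,
       flags = paste(flags, collapse = ";"))
}

#' Assign XCI status to the members of a profiled cluster
#'
#' Base rule from the cluster's evidence classes: hypermethylated with
#' high XIST is a preserved Xi; partial demethylation with high XIST is
#' partial Xi reactivation (Xa+); hypomethylation with low XIST is two
#' active X chromosomes — unless both arms are deleted, in which case the
#' sample is an "Xa-only" whole-Xi loss reported as preserved-Xi
#' equivalent. A member of a partial or hypomethylated cluster whose
#' selective arm hypomethylation coincides with a deletion call on the
#' same arm is reassigned to preserved Xi (`override_applied = TRUE`):
#' the deletion removed that arm of the Xi while the remaining Xi is
#' intact. Conflicting evidence (hypo + high XIST, hyper + low XIST) is
#' resolved by the methylation class and flagged; members without XIST
#' data are classified by methylation and copy number alone and flagged
#' low-confidence.
#'
#' @param profile an `xci_cluster_profile` from [profile_cluster()].
#' @param arm_calls `data.frame` with one row per member: `sample_id`,
#'   `p_arm_cnv`, `q_arm_cnv`, `p_arm_meth`, `q_arm_meth`.
#' @return calls `data.frame`, one row per member.
#' @export
assign_status <- function(profile, arm_calls) {
  stopifnot(inherits(profile, "xci_cluster_profile"))
  idx <- match(profile$member_samples, arm_calls$sample_id)
  assert_that(!anyNA(idx), "arm calls missing for cluster member(s)")
  rows <- lapply(idx, function(i) {
    a <- arm_calls[i, ]
    res <- assign_one(profile$meth_class, profile$xist_class,
                      as.character(a$p_arm_cnv), as.character(a$q_arm_cnv),
                      as.character(a$p_arm_meth), as.character(a$q_arm_meth))
    data.frame(sample_id = a$sample_id, histology = profile$histology,
               cluster = profile$cluster_id,
               meth_class = profile$meth_class, xist_class = profile$xist_class,
               p_arm_cnv = a$p_arm_cnv, q_arm_cnv = a$q_arm_cnv,
               p_arm_meth = a$p_arm_meth, q_arm_meth = a$q_arm_meth,
               xci_group = res$xci_group,
               override_applied = res$override_applied,
               flags = res$flags, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Classify a cohort by X-chromosome-inactivation status
#'
#' The end-to-end inference: samples are stratified by histology; within
#' each stratum the X-linked CpG-island betas are imputed and clustered
#' (complete linkage, Euclidean, `k` clusters); clusters are profiled
#' with methylation and XIST evidence; per-sample arm-level copy-number
#' and hypomethylation calls are made; and each sample receives one call.
#'
#' Two assignment modes share the same rule set (see [assign_status()]):
#' \describe{
#'   \item{`"sample"` (default)}{the methylation and XIST classes entering
#'     the rules are the sample's own (mean X-island beta, own XIST
#'     level). Robust when a cluster mixes states — in particular when
#'     Xi-arm-deletion cases distort the cluster structure at small `k`.}
#'   \item{`"cluster"`}{the classes are the cluster's, so all members of
#'     a cluster share a base assignment and only the arm-deletion
#'     override acts per sample — the published narrative.}
#' }
#' Cluster ids, profiles and both evidence sets are retained either way.
#'
#' @param methylation probes x samples beta matrix.
#' @param manifest probe manifest (see [read_manifest()]).
#' @param clinical clinical table with `sample_id` and `histology`.
#' @param seg optional SEG `data.frame`; without it all arms are neutral.
#' @param expression optional RSEM matrix containing a `XIST` row.
#' @param k clusters per histology stratum.
#' @param thresholds from [xci_thresholds()].
#' @param arms from [xci_arm_def()].
#' @param assignment `"sample"` or `"cluster"`.
#' @return object of class `xci_fit`; `as.data.frame()` extracts the
#'   calls table, `summary()` the cluster profiles and group counts.
#' @examples
#' cohort <- simulate_xci_cohort(xci_sim_config(n_per_cell = 10, seed = 7))
#' fit <- xci_classify(cohort$methylation, cohort$manifest, cohort$clinical,
#'                     seg = cohort$seg, expression = cohort$expression)
#' table(as.data.frame(fit)$xci_group, cohort$truth$true_xci)
#' @export
xci_classify <- function(methylation, manifest, clinical,
                         seg = NULL, expression = NULL, k = 3,
                         thresholds = xci_thresholds(),
                         arms = xci_arm_def(),
                         assignment = c("sample", "cluster")) {
  assignment <- match.arg(assignment)
  samples <- intersect(colnames(methylation), clinical$sample_id)
  n_drop <- length(union(colnames(methylation), clinical$sample_id)) - length(samples)
  if (n_drop > 0) xci_log("restricting to %d samples shared by methylation and clinical (%d dropped)",
                          length(samples), n_drop)
  assert_that(length(samples) > 0, "no samples shared between methylation and clinical")
  clin <- clinical[match(samples, clinical$sample_id), ]

  x_probes <- select_probes(manifest, "chrX", cpg_island_only = TRUE)
  x_probes <- intersect(x_probes, rownames(methylation))
  assert_that(length(x_probes) > 0, "no X-linked CpG-island probes in the methylation matrix")

  xist_log <- rep(NA_real_, length(samples))
  names(xist_log) <- samples
  if (!is.null(expression) && "XIST" %in% rownames(expression)) {
    common <- intersect(samples, colnames(expression))
    xist_log[common] <- log2p1(expression["XIST", common])
  }

  calls <- NULL
  profiles <- list()
  for (h in levels(droplevels(factor(clin$histology)))) {
    ids <- samples[clin$histology == h]
    if (length(ids) < k) {
      stop_xci("histology stratum '%s' has %d samples but k = %d; reduce k",
               h, length(ids), k)
    }
    sub <- impute_missing(methylation[x_probes, ids, drop = FALSE])
    lab <- cluster_samples(sub, k)
    mean_beta <- colMeans(sub)

    arm_tab <- do.call(rbind, lapply(ids, function(sid) {
      cnv <- if (is.null(seg)) c(p = "neutral", q = "neutral")
      else call_arm_cnv(seg, sid, arms, thresholds)
      meth <- detect_arm_hypomethylation(methylation[, sid], manifest, arms,
                                         thresholds$t_hypo)
      data.frame(sample_id = sid, p_arm_cnv = cnv[["p"]], q_arm_cnv = cnv[["q"]],
                 p_arm_meth = meth[["p"]], q_arm_meth = meth[["q"]],
                 stringsAsFactors = FALSE)
    }))

    # order clusters by decreasing median methylation for stable naming
    med_by_cl <- vapply(seq_len(max(lab)), function(ci) {
      stats::median(mean_beta[names(lab)[lab == ci]])
    }, 0)
    rank_of <- rank(-med_by_cl, ties.method = "first")
    for (ci in seq_len(max(lab))) {
      members <- names(lab)[lab == ci]
      cl_id <- sprintf("%s_%d", substr(h, 1, 1), rank_of[ci])
      prof <- profile_cluster(members, mean_beta, xist_log, thresholds,
                              cluster_id = cl_id, histology = h)
      profiles[[cl_id]] <- prof
      if (assignment == "cluster") {
        calls <- rbind(calls, assign_status(prof, arm_tab))
      } else {
        rows <- lapply(members, function(sid) {
          a <- arm_tab[arm_tab$sample_id == sid, ]
          mc <- meth_class_of(mean_beta[[sid]], thresholds)
          xc <- if (is.na(xist_log[[sid]])) "unknown"
          else if (xist_log[[sid]] >= thresholds$t_xist) "high" else "low"
          res <- assign_one(mc, xc, a$p_arm_cnv, a$q_arm_cnv,
                            a$p_arm_meth, a$q_arm_meth)
          data.frame(sample_id = sid, histology = h, cluster = cl_id,
                     meth_class = mc, xist_class = xc,
                     p_arm_cnv = a$p_arm_cnv, q_arm_cnv = a$q_arm_cnv,
                     p_arm_meth = a$p_arm_meth, q_arm_meth = a$q_arm_meth,
                     xci_group = res$xci_group,
                     override_applied = res$override_applied,
                     flags = res$flags, stringsAsFactors = FALSE)
        })
        calls <- rbind(calls, do.call(rbind, rows))
      }
    }
  }
  calls <- calls[order(calls$sample_id), ]
  rownames(calls) <- NULL
  structure(list(calls = calls, profiles = profiles, k = k,
                 thresholds = thresholds, arms = arms,
                 assignment = assignment,
                 n_probes = length(x_probes),
                 xist_log = xist_log),
            class = "xci_fit")
}

#' @export
print.xci_fit <- function(x, ...) {
  cat("XCI status classification (", x$assignment, "-level assignment, k = ",
      x$k, " per stratum, ", x$n_probes, " X-island probes)\n\n", sep = "")
  print(table(x$calls$histology, x$calls$xci_group))
  n_ov <- sum(x$calls$override_applied)
  if (n_ov > 0) cat("\n", n_ov, "sample(s) rescued by the Xi-arm-deletion override\n")
  invisible(x)
}

#' @export
summary.xci_fit <- function(object, ...) {
  prof <- do.call(rbind, lapply(object$profiles, function(p) {
    data.frame(cluster = p$cluster_id, histology = p$histology,
               n = length(p$member_samples),
               median_mean_beta = round(p$median_sample_mean_beta, 3),
               meth_class = p$meth_class, xist_class = p$xist_class,
               stringsAsFactors = FALSE)
  }))
  rownames(prof) <- NULL
  out <- list(clusters = prof,
              groups = table(object$calls$histology, object$calls$xci_group),
              n_override = sum(object$calls$override_applied),
              n_flagged = sum(nzchar(object$calls$flags)))
  class(out) <- "summary.xci_fit"
  out
}

#' @export
print.summary.xci_fit <- function(x, ...) {
  cat("Cluster profiles:\n")
  print(x$clusters)
  cat("\nXCI group by histology:\n")
  print(x$groups)
  cat("\nOverrides applied:", x$n_override,
      " Flagged calls:", x$n_flagged, "\n")
  invisible(x)
}

#' @export
as.data.frame.xci_fit <- function(x, ...) x$calls

#' Diagnostic plot of an XCI classification
#'
#' Scatter of per-sample XIST log2 expression against mean X-island beta,
#' colored by assigned group — the two axes of evidence the assignment
#' rules read.
#'
#' @param x an `xci_fit`.
#' @param methylation the beta matrix the fit was made from.
#' @param manifest the probe manifest.
#' @param ... passed to [graphics::plot()].
#' @export
plot.xci_fit <- function(x, methylation, manifest, ...) {
  probes <- intersect(select_probes(manifest, "chrX"), rownames(methylation))
  mb <- colMeans(methylation[probes, x$calls$sample_id, drop = FALSE], na.rm = TRUE)
  col <- c(preserved_Xi = "#1b9e77", Xa_plus = "#d95f02", two_Xa = "#7570b3")
  graphics::plot(mb, x$xist_log[x$calls$sample_id],
                 col = col[x$calls$xci_group], pch = 19,
                 xlab = "mean X CpG-island beta",
                 ylab = "XIST log2(RSEM + 1)", ...)
  graphics::abline(v = c(x$thresholds$t_hypo, x$thresholds$t_hyper), lty = 3)
  graphics::abline(h = x$thresholds$t_xist, lty = 3)
  graphics::legend("bottomright", names(col), col = col, pch = 19, bty = "n")
  invisible(x)
}
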