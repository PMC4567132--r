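#' Per-sample mean panel expression
#'
#' The panel summary is the mean over panel genes of log2(RSEM + 1)
#' (mean of logs, not log of mean). Panel genes absent from the matrix
#' are dropped with a logged count; an entirely absent panel is an error.
#'
#' @param expression genes x samples RSEM matrix.
#' @param panel a panel list from [read_panel()] or a character vector of
#'   gene ids.
#' @param samples sample ids; default all columns.
#' @return named numeric vector, one value per sample.
#' @export
mean_panel_expression <- function(expression, panel, samples = colnames(expression)) {
  genes <- if (is.list(panel)) panel$genes else panel
  genes <- unique(genes)
  present <- intersect(genes, rownames(expression))
  if (length(present) == 0) stop_xci("no panel gene present in expression matrix")
  if (length(present) < length(genes)) {
    xci_log("panel '%s': %d gene(s) absent from expression matrix",
            if (is.list(panel)) panel$name else "panel",
            length(genes) - length(present))
  }
  colMeans(log2p1(expression[present, samples, drop = FALSE]))
}

#' Per-sample mean CpG-island methylation
#'
#' Mean beta over a probe subset, skipping missing entries per sample.
#'
#' @param methylation probes x samples beta matrix.
#' @param probes probe ids (e.g. from [select_probes()]).
#' @param samples sample ids; default all columns.
#' @return named numeric vector, one value per sample.
#' @export
mean_cpg_methylation <- function(methylation, probes, samples = colnames(methylation)) {
  probes <- intersect(probes, rownames(methylation))
  if (length(probes) == 0) stop_xci("no requested probe present in methylation matrix")
  m <- methylation[probes, samples, drop = FALSE]
  out <- colMeans(m, na.rm = TRUE)
  if (anyNA(out) || any(!is.finite(out))) {
    stop_xci("sample '%s' has no non-missing value over the probe subset",
             samples[which(!is.finite(out))[1]])
  }
  out
}

#' Significance band for a p-value
#'
#' The figure-legend convention: `NS` (not significant), `*` p < 0.05,
#' `**` p < 0.01, `***` p < 0.001.
#'
#' @param p p-value(s).
#' @return character vector of bands.
#' @export
significance_band <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "NS")))
}

#' Compare a statistic across groups
#'
#' Two groups are compared by a two-sided Welch (unequal-variance) t-test;
#' three or more by classical one-way ANOVA. When every value is identical
#' (within machine epsilon) the comparison is degenerate and p = 1 by
#' convention. With `pairwise = TRUE` all pairwise Welch tests are also
#' returned (the per-pair stars of the box plots).
#'
#' @param values numeric vector.
#' @param groups factor/character of the same length.
#' @param pairwise also compute pairwise Welch tests (default for >= 3
#'   groups when `pairwise = TRUE`).
#' @return list of class `xci_group_comparison`: per-group summaries,
#'   test name (`welch_t` or `anova_oneway`), statistic, `p_value`,
#'   `band`, and optionally `pairwise`.
#' @export
compare_groups <- function(values, groups, pairwise = FALSE) {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  groups <- droplevels(factor(groups[keep]))
  lv <- levels(groups)
  assert_that(length(lv) >= 2, "need at least 2 groups (got %d)", length(lv))
  n_by <- table(groups)
  if (any(n_by < 2)) {
    stop_xci("group '%s' has fewer than 2 values", names(n_by)[n_by < 2][1])
  }
  summ <- do.call(rbind, lapply(lv, function(g) {
    v <- values[groups == g]
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(group = g, n = length(v), mean = mean(v), median = q[2],
               q25 = q[1], q75 = q[3], stringsAsFactors = FALSE)
  }))
  degenerate <- (max(values) - min(values)) < .Machine$double.eps^0.5
  if (degenerate) {
    test <- if (length(lv) == 2) "welch_t" else "anova_oneway"
    stat <- 0; p <- 1
  } else if (length(lv) == 2) {
    tt <- stats::t.test(values ~ groups)
    test <- "welch_t"; stat <- unname(tt$statistic); p <- tt$p.value
  } else {
    ft <- stats::oneway.test(values ~ groups, var.equal = TRUE)
    test <- "anova_oneway"; stat <- unname(ft$statistic); p <- ft$p.value
  }
  out <- list(groups = summ, test = test, statistic = stat,
              p_value = p, band = significance_band(p), degenerate = degenerate)
  if (pairwise && length(lv) >= 2 && !degenerate) {
    prs <- utils::combn(lv, 2, simplify = FALSE)
    out$pairwise <- do.call(rbind, lapply(prs, function(pr) {
      vi <- values[groups == pr[1]]; vj <- values[groups == pr[2]]
      if ((max(c(vi, vj)) - min(c(vi, vj))) < .Machine$double.eps^0.5) {
        p_ij <- 1
      } else {
        p_ij <- stats::t.test(vi, vj)$p.value
      }
      data.frame(group1 = pr[1], group2 = pr[2], p_value = p_ij,
                 band = significance_band(p_ij), stringsAsFactors = FALSE)
    }))
  }
  class(out) <- "xci_group_comparison"
  out
}

#' @export
print.xci_group_comparison <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g [%s]%s\n", x$test, x$statistic,
              x$p_value, x$band, if (x$degenerate) " (degenerate)" else ""))
  print(x$groups, row.names = FALSE)
  if (!is.null(x$pairwise)) {
    cat("pairwise Welch tests:\n")
    print(x$pairwise, row.names = FALSE)
  }
  invisible(x)
}

#' Panel-expression comparisons across groupings
#'
#' For every panel and every grouping (XCI group, histology, TCGA
#' subtype) computes per-sample panel means and the group comparison,
#' returning one long-format row per panel x grouping. Per-sample means
#' are attached as the `"sample_means"` attribute for plotting or export.
#'
#' @param calls calls `data.frame` (from [xci_classify()]).
#' @param expression genes x samples RSEM matrix.
#' @param panels list of panels (each as from [read_panel()]).
#' @param clinical optional clinical table contributing `tcga_subtype`.
#' @return `data.frame` with columns `panel`, `grouping`, `test`,
#'   `statistic`, `p_value`, `band`, `n`.
#' @export
expression_by_group_table <- function(calls, expression, panels,
                                      clinical = NULL) {
  samples <- intersect(calls$sample_id, colnames(expression))
  if (length(samples) == 0) stop_xci("no samples shared between calls and expression")
  cl <- calls[match(samples, calls$sample_id), ]
  groupings <- list(xci_group = cl$xci_group, histology = cl$histology)
  if (!is.null(clinical) && "tcga_subtype" %in% names(clinical)) {
    groupings$tcga_subtype <- clinical$tcga_subtype[match(samples, clinical$sample_id)]
  }
  sample_means <- list()
  rows <- list()
  for (p in panels) {
    pm <- mean_panel_expression(expression, p, samples)
    sample_means[[p$name]] <- pm
    for (gname in names(groupings)) {
      g <- droplevels(factor(groupings[[gname]]))
      if (nlevels(g) < 2) stop_xci("grouping '%s' has a single level", gname)
      cmp <- compare_groups(pm, g, pairwise = identical(gname, "xci_group"))
      rows[[length(rows) + 1]] <- data.frame(panel = p$name, grouping = gname,
                                             test = cmp$test,
                                             statistic = cmp$statistic,
                                             p_value = cmp$p_value,
                                             band = cmp$band,
                                             n = sum(!is.na(pm) & !is.na(g)),
                                             stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "sample_means") <- sample_means
  out
}
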