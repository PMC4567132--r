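#' Cross-tabulate a categorical covariate against XCI group
#'
#' Counts and column percentages per XCI group, with missing values
#' dropped (complete-case per field) and the effective N recorded — the
#' per-field "N =" convention of clinical characteristic tables.
#'
#' @param field categorical values, one per sample.
#' @param xci_group XCI group labels, aligned with `field`.
#' @param drop_missing drop pairs with a missing entry (default `TRUE`).
#' @return list of class `xci_crosstab`: `counts` (field levels x
#'   groups), `col_pct`, `n`, `degenerate` (single field level).
#' @export
xci_crosstab <- function(field, xci_group, drop_missing = TRUE) {
  if (is.numeric(field)) {
    stop_xci("field is continuous; use anova_by_group() for continuous covariates")
  }
  f <- factor(field)
  g <- factor(xci_group)
  keep <- if (drop_missing) !is.na(f) & !is.na(g) else rep(TRUE, length(f))
  f <- droplevels(f[keep]); g <- droplevels(g[keep])
  counts <- table(f, g, dnn = NULL)
  col_pct <- 100 * sweep(counts, 2, pmax(colSums(counts), 1), "/")
  structure(list(counts = unclass(counts), col_pct = unclass(col_pct),
                 n = sum(counts), degenerate = nrow(counts) < 2),
            class = "xci_crosstab")
}

#' @export
print.xci_crosstab <- function(x, digits = 1, ...) {
  cat("Cross-tabulation (N =", x$n, ")\n")
  disp <- matrix(sprintf("%d (%.*f%%)", x$counts, digits, x$col_pct),
                 nrow = nrow(x$counts), dimnames = dimnames(x$counts))
  print(disp, quote = FALSE)
  if (x$degenerate) cat("(degenerate: single field level)\n")
  invisible(x)
}

#' Exact r x c contingency test
#'
#' The generalized Fisher exact test: conditional on the margins, the
#' p-value sums the multivariate hypergeometric probabilities of all
#' tables no more probable than the observed one. Computed by exact
#' enumeration (network algorithm) where feasible; larger tables fall
#' back to conditional Monte Carlo with `B` draws and a mandatory seed.
#' A table with a zero row or column margin carries no information and
#' returns p = 1 with a degenerate flag.
#'
#' @param x counts: a matrix, `table`, or an [xci_crosstab()].
#' @param mc_threshold bound on the enumerable-table count above which
#'   Monte Carlo is used (unless the total N is small enough for the
#'   network algorithm regardless).
#' @param exact_n_max total-count bound under which exact computation is
#'   always attempted first.
#' @param B Monte-Carlo draws.
#' @param seed seed for the Monte-Carlo path (required when used).
#' @return list: `p_value` in (0, 1], `method` (`"exact"` or
#'   `"monte_carlo"`), `degenerate`.
#' @export
fisher_exact_rxc <- function(x, mc_threshold = 1e7, exact_n_max = 1000,
                             B = 1e6, seed = NULL) {
  if (inherits(x, "xci_crosstab")) x <- x$counts
  x <- as.matrix(x)
  if (any(x < 0)) stop_xci("contingency table has negative counts")
  if (any(x != round(x))) stop_xci("contingency table has non-integer counts")
  if (nrow(x) < 2 || ncol(x) < 2) stop_xci("need at least a 2 x 2 table")
  if (sum(x) == 0 || any(rowSums(x) == 0) || any(colSums(x) == 0)) {
    return(list(p_value = 1, method = "degenerate", degenerate = TRUE))
  }
  n_tables <- count_margin_tables_bound(rowSums(x), colSums(x))
  if (sum(x) <= exact_n_max || n_tables <= mc_threshold) {
    p <- tryCatch(
      stats::fisher.test(x, workspace = 2e7)$p.value,
      error = function(e) NA_real_)
    if (!is.na(p)) {
      return(list(p_value = min(max(p, .Machine$double.xmin), 1),
                  method = "exact", degenerate = FALSE))
    }
  }
  if (is.null(seed)) stop_xci("Monte-Carlo fallback requires a seed")
  p <- withr_seed(seed, stats::fisher.test(x, simulate.p.value = TRUE, B = B)$p.value)
  list(p_value = min(max(p, 1 / (B + 1)), 1), method = "monte_carlo",
       degenerate = FALSE)
}

# upper bound on the number of tables with the given margins:
# product over rows of the compositions bound, capped to avoid overflow
count_margin_tables_bound <- function(rs, cs) {
  lb <- sum(lchoose(rs + length(cs) - 1, length(cs) - 1))
  if (lb > log(1e15)) Inf else exp(lb)
}

# evaluate expr under a local RNG seed without disturbing the caller's stream
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' One-way ANOVA of a continuous covariate across XCI groups
#'
#' @param values numeric covariate.
#' @param groups group labels aligned with `values`.
#' @return list: `statistic` (F), `p_value`, `df`, `degenerate` (constant
#'   covariate, p = 1).
#' @export
anova_by_group <- function(values, groups) {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  groups <- droplevels(factor(groups[keep]))
  assert_that(nlevels(groups) >= 2, "need at least 2 groups")
  if (any(table(groups) < 2)) stop_xci("every group needs at least 2 values")
  if ((max(values) - min(values)) < .Machine$double.eps^0.5) {
    return(list(statistic = 0, p_value = 1, df = c(nlevels(groups) - 1L,
                                                   length(values) - nlevels(groups)),
                degenerate = TRUE))
  }
  ft <- stats::oneway.test(values ~ groups, var.equal = TRUE)
  list(statistic = unname(ft$statistic), p_value = ft$p.value,
       df = unname(ft$parameter), degenerate = FALSE)
}

#' Kaplan-Meier curves and k-group log-rank test
#'
#' @param time follow-up times (days, >= 0).
#' @param event event indicators (logical or 0/1).
#' @param group group labels.
#' @return list of class `xci_survfit`: `curves` (long `data.frame` of
#'   time / at-risk / survival per group), `logrank_chisq`, `df`,
#'   `p_value`, and the underlying `survfit` object.
#' @export
km_logrank <- function(time, event, group) {
  keep <- !is.na(time) & !is.na(event) & !is.na(group)
  time <- time[keep]; event <- as.integer(event[keep])
  group <- droplevels(factor(group[keep]))
  assert_that(all(time >= 0), "times must be >= 0")
  assert_that(nlevels(group) >= 2, "need at least 2 groups")
  if (sum(event) == 0) stop_xci("no events in the cohort; survival analysis impossible")
  ev_by <- tapply(event, group, sum)
  if (any(ev_by == 0)) {
    xci_log("group(s) with zero events included: %s",
            paste(names(ev_by)[ev_by == 0], collapse = ", "))
  }
  df <- data.frame(time = time, event = event, group = group)
  sf <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  k <- nlevels(group)
  p <- stats::pchisq(sd$chisq, df = k - 1, lower.tail = FALSE)
  strata_lab <- rep(sub("^group=", "", names(sf$strata)), sf$strata)
  curves <- data.frame(group = strata_lab, time = sf$time,
                       n_risk = sf$n.risk, survival = sf$surv)
  structure(list(curves = curves, logrank_chisq = unname(sd$chisq),
                 df = k - 1L, p_value = p, survfit = sf),
            class = "xci_survfit")
}

#' @export
print.xci_survfit <- function(x, ...) {
  cat(sprintf("log-rank test: chisq = %.4g on %d df, p = %.4g\n",
              x$logrank_chisq, x$df, x$p_value))
  invisible(x)
}

#' @export
plot.xci_survfit <- function(x, ...) {
  graphics::plot(x$survfit, col = seq_along(x$survfit$strata),
                 xlab = "days", ylab = "survival", ...)
  graphics::legend("bottomleft", sub("^group=", "", names(x$survfit$strata)),
                   col = seq_along(x$survfit$strata), lty = 1, bty = "n")
  invisible(x)
}

#' Stage-adjusted Cox proportional-hazards model
#'
#' Cox regression of survival on clinical stage (reference I-II) and XCI
#' group (reference preserved Xi), Efron tie handling. Returns hazard
#' ratios with 95% confidence intervals and Wald p-values per term.
#'
#' @param time,event as in [km_logrank()].
#' @param xci_group XCI group labels (levels preserved_Xi / Xa_plus /
#'   two_Xa; reference preserved_Xi).
#' @param stage stage labels (levels I_II / III / IV; reference I_II).
#' @return list of class `xci_cox`: `terms` `data.frame` (term, hr, lo,
#'   hi, p), `converged`, and the `coxph` fit.
#' @export
cox_stage_adjusted <- function(time, event, xci_group, stage) {
  keep <- !is.na(time) & !is.na(event) & !is.na(xci_group) & !is.na(stage)
  df <- data.frame(time = time[keep], event = as.integer(event[keep]),
                   xci_group = factor(as.character(xci_group[keep]), XCI_GROUPS),
                   stage = factor(as.character(stage[keep]), STAGES))
  assert_that(all(df$time >= 0), "times must be >= 0")
  if (sum(df$event) == 0) stop_xci("no events in the cohort; Cox model impossible")
  fit <- tryCatch(
    survival::coxph(survival::Surv(time, event) ~ stage + xci_group,
                    data = df, ties = "efron"),
    error = function(e) stop_xci("Cox model failed: %s", conditionMessage(e)))
  separation <- any(!is.finite(coef(fit))) || any(abs(coef(fit)) > 15)
  if (separation) xci_log("possible complete separation in Cox fit (extreme coefficient)")
  ci <- suppressMessages(stats::confint(fit))
  sm <- summary(fit)
  terms <- data.frame(term = rownames(ci),
                      hr = exp(coef(fit)),
                      lo = exp(ci[, 1]), hi = exp(ci[, 2]),
                      p = sm$coefficients[, "Pr(>|z|)"],
                      stringsAsFactors = FALSE)
  rownames(terms) <- NULL
  structure(list(terms = terms, converged = !separation, fit = fit),
            class = "xci_cox")
}

#' @export
print.xci_cox <- function(x, ...) {
  t <- x$terms
  t$hr <- sprintf("%.2f (%.2f-%.2f)", t$hr, t$lo, t$hi)
  t$p <- signif(t$p, 3)
  print(t[, c("term", "hr", "p")], row.names = FALSE)
  if (!x$converged) cat("warning: possible separation / non-convergence\n")
  invisible(x)
}
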