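#' Configuration for the synthetic cohort generator
#'
#' Defaults encode the study conditions the generator emulates: X-linked
#' CpG islands half-methylated under a preserved Xi (mean beta 0.45),
#' partially demethylated under Xi reactivation (0.25), and hypomethylated
#' with two active X chromosomes (0.10); XIST log2 expression centered at
#' 7.9 / 8.3 / 5.4 for the three states; a small fraction of preserved-Xi
#' tumors carrying an Xi arm deletion (selective arm hypomethylation plus
#' a deleted SEG segment, XIST kept high); autosomal CpG-island
#' methylation mildly decreasing with XCI loss; CTA expression coupled to
#' global (autosomal) hypomethylation only; and survival with stage as a
#' confounder and a loss-of-XCI hazard ratio of 1.6.
#'
#' @param n_per_cell samples per histology-by-state cell (6 cells).
#' @param n_x_island_probes,n_autosomal_island_probes CpG-island probe counts.
#' @param n_nonisland_probes non-island probes (uninformative, beta ~ 0.5).
#' @param beta_means named per-state mean beta for X-island probes.
#' @param beta_concentration Beta-distribution pseudo-count scale; probe
#'   betas are drawn Beta(mean * c, (1 - mean) * c).
#' @param xist_log_mean,xist_log_sd per-state mean and common sd of XIST
#'   log2(RSEM + 1) expression.
#' @param autosomal_island_mean per-state mean beta for autosomal islands.
#' @param cta_slope slope coupling CTA log2 expression to
#'   (1 - sample mean autosomal island beta).
#' @param cta_log_sd sd of CTA log-expression noise.
#' @param n_xcta,n_auto_cta panel sizes (48 X-linked, 8 autosomal).
#' @param xi_arm_deletion_fraction fraction of preserved-Xi samples given
#'   an Xi arm deletion (arm chosen at random).
#' @param seg_mean_deleted,seg_mean_neutral_sd SEG log2 means.
#' @param centromere,chrom_length synthetic chrX geometry (bp).
#' @param os_baseline_rate,dfs_baseline_rate exponential hazards per day
#'   for stage I-II preserved-Xi patients.
#' @param stage_hr named hazard ratios for stages III and IV.
#' @param xci_hr hazard ratio applied to both XCI-loss states.
#' @param stage_probs 3 x 3 matrix of stage distribution per state
#'   (rows = states, cols = I_II/III/IV); the default is stage-confounded.
#' @param censor_range administrative censoring window (days).
#' @param age_mean,age_sd per-state age distributions (years).
#' @param seed mandatory integer seed.
#' @return a validated `xci_sim_config` list.
#' @export
xci_sim_config <- function(n_per_cell = 60,
                           n_x_island_probes = 500,
                           n_autosomal_island_probes = 2000,
                           n_nonisland_probes = 100,
                           beta_means = c(preserved_Xi = 0.45,
                                          Xa_plus = 0.25,
                                          two_Xa = 0.10),
                           beta_concentration = 50,
                           xist_log_mean = c(preserved_Xi = 7.9,
                                             Xa_plus = 8.3,
                                             two_Xa = 5.4),
                           xist_log_sd = 1.0,
                           autosomal_island_mean = c(preserved_Xi = 0.35,
                                                     Xa_plus = 0.28,
                                                     two_Xa = 0.25),
                           cta_slope = 6.0,
                           cta_log_sd = 0.5,
                           n_xcta = 48,
                           n_auto_cta = 8,
                           xi_arm_deletion_fraction = 0.05,
                           seg_mean_deleted = -0.8,
                           seg_mean_neutral_sd = 0.05,
                           centromere = 6e7,
                           chrom_length = 1.55e8,
                           os_baseline_rate = 1e-4,
                           dfs_baseline_rate = 1.5e-4,
                           stage_hr = c(III = 4.24, IV = 7.31),
                           xci_hr = 1.6,
                           stage_probs = rbind(preserved_Xi = c(0.744, 0.203, 0.053),
                                               Xa_plus = c(0.667, 0.294, 0.039),
                                               two_Xa = c(0.632, 0.263, 0.105)),
                           censor_range = c(1000, 4000),
                           age_mean = c(preserved_Xi = 62.2,
                                        Xa_plus = 69.8,
                                        two_Xa = 68.9),
                           age_sd = c(preserved_Xi = 11.4,
                                      Xa_plus = 9.1,
                                      two_Xa = 8.8),
                           seed = NULL) {
  cfg <- as.list(environment())
  if (is.null(cfg$seed)) stop_xci("simulation seed is mandatory")
  cfg$seed <- as.integer(cfg$seed)
  if (length(cfg$n_per_cell) == 1) {
    cfg$n_per_cell <- matrix(cfg$n_per_cell, 2, 3,
                             dimnames = list(HISTOLOGIES, XCI_GROUPS))
  }
  assert_that(all(cfg$n_per_cell >= 0), "sample counts must be >= 0")
  assert_that(sum(cfg$n_per_cell) > 0, "at least one histology-by-state cell must be non-empty")
  for (nm in c("beta_means", "autosomal_island_mean")) {
    v <- cfg[[nm]]
    assert_that(all(XCI_GROUPS %in% names(v)), "%s must name all three states", nm)
    assert_that(all(v > 0 & v < 1), "%s must lie in (0, 1)", nm)
  }
  assert_that(cfg$beta_concentration > 0, "beta_concentration must be > 0")
  assert_that(cfg$xi_arm_deletion_fraction >= 0 && cfg$xi_arm_deletion_fraction <= 1,
              "xi_arm_deletion_fraction must be in [0, 1]")
  assert_that(cfg$centromere > 0 && cfg$centromere < cfg$chrom_length,
              "centromere must fall inside the chromosome")
  assert_that(all(abs(rowSums(cfg$stage_probs) - 1) < 1e-8),
              "stage_probs rows must sum to 1")
  class(cfg) <- "xci_sim_config"
  cfg
}

#' Generate a complete synthetic cohort with known XCI ground truth
#'
#' Produces every artifact the classification and downstream stages
#' consume: a probe manifest, a beta-value matrix, an RSEM expression
#' matrix (XIST, CTA panels and background genes), chrX SEG records,
#' a clinical table with stage-confounded survival, and the true state of
#' each sample. Xi-arm-deletion samples are generated inside the
#' preserved-Xi truth state: the deleted arm's island probes take the
#' two-Xa mean while XIST stays high, and a matching deleted SEG segment
#' spans the arm — so the classifier's override rule is directly testable.
#' Fully reproducible from `config$seed`.
#'
#' @param config an [xci_sim_config()].
#' @return list of class `xci_cohort` with elements `methylation`,
#'   `expression`, `seg`, `clinical`, `manifest`, `truth`, `panels`,
#'   `config`.
#' @export
simulate_xci_cohort <- function(config) {
  stopifnot(inherits(config, "xci_sim_config"))
  cfg <- config
  set.seed(cfg$seed)
  manifest <- sim_manifest(cfg)
  truth <- sim_truth(cfg)
  n <- nrow(truth)

  beta <- sim_methylation(cfg, manifest, truth)
  seg <- sim_seg(cfg, truth)
  expr_panels <- sim_expression(cfg, truth, beta, manifest)
  clinical <- sim_clinical(cfg, truth)

  structure(list(methylation = beta,
                 expression = expr_panels$expression,
                 seg = seg,
                 clinical = clinical,
                 manifest = manifest,
                 truth = truth,
                 panels = expr_panels$panels,
                 config = cfg),
            class = "xci_cohort")
}

sim_manifest <- function(cfg) {
  nx <- cfg$n_x_island_probes
  na <- cfg$n_autosomal_island_probes
  nn <- cfg$n_nonisland_probes
  x_pos <- sort(round(stats::runif(nx, 1, cfg$chrom_length)))
  auto_chr <- sample(paste0("chr", 1:22), na, replace = TRUE)
  auto_pos <- round(stats::runif(na, 1, 2.4e8))
  non_chr <- sample(CHROMOSOMES, nn, replace = TRUE)
  non_pos <- round(stats::runif(nn, 1, 1.5e8))
  data.frame(probe_id = c(sprintf("cgX%04d", seq_len(nx)),
                          sprintf("cgA%04d", seq_len(na)),
                          sprintf("cgN%04d", seq_len(nn))),
             chrom = c(rep("chrX", nx), auto_chr, non_chr),
             pos = as.integer(c(x_pos, auto_pos, non_pos)),
             cpg_island = rep(c(TRUE, TRUE, FALSE), c(nx, na, nn)),
             stringsAsFactors = FALSE)
}

sim_truth <- function(cfg) {
  cells <- expand.grid(true_xci = XCI_GROUPS, histology = HISTOLOGIES,
                       stringsAsFactors = FALSE)[, 2:1]
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    k <- cfg$n_per_cell[cells$histology[i], cells$true_xci[i]]
    if (k == 0) return(NULL)
    data.frame(histology = cells$histology[i], true_xci = cells$true_xci[i],
               stringsAsFactors = FALSE)[rep(1, k), , drop = FALSE]
  })
  truth <- do.call(rbind, rows)
  truth$sample_id <- sprintf("T%04d", seq_len(nrow(truth)))
  rownames(truth) <- NULL
  truth$xi_arm_deleted <- "none"
  pres <- which(truth$true_xci == "preserved_Xi")
  n_del <- round(length(pres) * cfg$xi_arm_deletion_fraction)
  if (n_del > 0) {
    del <- sample(pres, n_del)
    truth$xi_arm_deleted[del] <- sample(c("p", "q"), n_del, replace = TRUE)
  }
  truth[, c("sample_id", "histology", "true_xci", "xi_arm_deleted")]
}

sim_methylation <- function(cfg, manifest, truth) {
  n <- nrow(truth)
  c0 <- cfg$beta_concentration
  rbeta_m <- function(k, m) stats::rbeta(k, m * c0, (1 - m) * c0)
  beta <- matrix(NA_real_, nrow(manifest), n,
                 dimnames = list(manifest$probe_id, truth$sample_id))
  is_x <- manifest$chrom == "chrX" & manifest$cpg_island
  is_auto <- manifest$chrom != "chrX" & manifest$cpg_island
  is_non <- !manifest$cpg_island
  x_p_arm <- is_x & manifest$pos < cfg$centromere
  for (i in seq_len(n)) {
    st <- truth$true_xci[i]
    beta[is_x, i] <- rbeta_m(sum(is_x), cfg$beta_means[[st]])
    del <- truth$xi_arm_deleted[i]
    if (del != "none") {
      on_arm <- if (del == "p") x_p_arm else (is_x & !x_p_arm)
      beta[on_arm, i] <- rbeta_m(sum(on_arm), cfg$beta_means[["two_Xa"]])
    }
    beta[is_auto, i] <- rbeta_m(sum(is_auto), cfg$autosomal_island_mean[[st]])
    beta[is_non, i] <- rbeta_m(sum(is_non), 0.5)
  }
  beta
}

sim_seg <- function(cfg, truth) {
  rows <- lapply(seq_len(nrow(truth)), function(i) {
    del <- truth$xi_arm_deleted[i]
    p_mean <- stats::rnorm(1, if (del == "p") cfg$seg_mean_deleted else 0,
                           cfg$seg_mean_neutral_sd)
    q_mean <- stats::rnorm(1, if (del == "q") cfg$seg_mean_deleted else 0,
                           cfg$seg_mean_neutral_sd)
    data.frame(sample_id = truth$sample_id[i], chrom = "chrX",
               start = c(1, cfg$centromere),
               end = c(cfg$centromere - 1, cfg$chrom_length),
               seg_mean = c(p_mean, q_mean), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

sim_expression <- function(cfg, truth, beta, manifest) {
  n <- nrow(truth)
  xcta <- sprintf("XCTA%02d", seq_len(cfg$n_xcta))
  acta <- sprintf("CTA%02d", seq_len(cfg$n_auto_cta))
  bg <- sprintf("GENE%03d", seq_len(50))
  genes <- c("XIST", xcta, acta, bg)
  expr <- matrix(NA_real_, length(genes), n, dimnames = list(genes, truth$sample_id))

  xist_log <- stats::rnorm(n, cfg$xist_log_mean[truth$true_xci], cfg$xist_log_sd)
  expr["XIST", ] <- pmax(2^pmax(xist_log, 0) - 1, 0)

  # CTA expression depends only on global (autosomal island) methylation,
  # not on XCI state per se: hypomethylation drives the panels.
  is_auto <- manifest$chrom != "chrX" & manifest$cpg_island
  auto_mean <- colMeans(beta[is_auto, , drop = FALSE])
  for (g in c(xcta, acta)) {
    lg <- cfg$cta_slope * (1 - auto_mean) + stats::rnorm(n, 0, cfg$cta_log_sd)
    expr[g, ] <- pmax(2^pmax(lg, 0) - 1, 0)
  }
  for (g in bg) {
    expr[g, ] <- pmax(2^stats::rnorm(n, 5, 1) - 1, 0)
  }
  list(expression = expr,
       panels = list(xcta = list(name = "xcta", genes = xcta, location = "X_linked"),
                     cta_autosomal = list(name = "cta_autosomal", genes = acta,
                                          location = "autosomal")))
}

sim_clinical <- function(cfg, truth) {
  n <- nrow(truth)
  st <- truth$true_xci
  stage <- vapply(st, function(s) {
    sample(STAGES, 1, prob = cfg$stage_probs[s, ])
  }, "")
  loss <- st != "preserved_Xi"
  stage_mult <- ifelse(stage == "III", cfg$stage_hr[["III"]],
                       ifelse(stage == "IV", cfg$stage_hr[["IV"]], 1))
  xci_mult <- ifelse(loss, cfg$xci_hr, 1)
  sim_out <- function(base_rate) {
    t_ev <- stats::rexp(n, base_rate * stage_mult * xci_mult)
    cens <- stats::runif(n, cfg$censor_range[1], cfg$censor_range[2])
    list(time = round(pmin(t_ev, cens), 1), event = t_ev <= cens)
  }
  os <- sim_out(cfg$os_baseline_rate)
  dfs <- sim_out(cfg$dfs_baseline_rate)
  meno <- ifelse(stats::runif(n) < 0.9, "post", sample(c("pre", "peri"), n, TRUE))
  data.frame(sample_id = truth$sample_id,
             histology = truth$histology,
             tcga_subtype = ifelse(truth$histology == "serous", "CN_high",
                                   sample(c("CN_low", "MSI", "POLE"), n, TRUE,
                                          prob = c(0.6, 0.3, 0.1))),
             age = round(stats::rnorm(n, cfg$age_mean[st], cfg$age_sd[st]), 1),
             stage = stage,
             menopause = meno,
             race = sample(c("white", "black", "asian"), n, TRUE,
                           prob = c(0.77, 0.18, 0.05)),
             ethnicity = sample(c("not_hispanic", "hispanic"), n, TRUE,
                                prob = c(0.97, 0.03)),
             residual = sample(c("R0", "R1", "R2", "RX"), n, TRUE,
                               prob = c(0.81, 0.06, 0.04, 0.09)),
             os_time = os$time, os_event = os$event,
             dfs_time = dfs$time, dfs_event = dfs$event,
             stringsAsFactors = FALSE)
}

#' Ground-truth table of a synthetic cohort
#'
#' @param truth either an `xci_cohort` or its `truth` component.
#' @return `data.frame` with one row per sample: `sample_id`, `histology`,
#'   `true_xci`, `xi_arm_deleted`.
#' @export
truth_table <- function(truth) {
  if (inherits(truth, "xci_cohort")) truth <- truth$truth
  as.data.frame(truth)
}

#' Simulate survival outcomes alone
#'
#' Light-weight generator for calibration studies of the survival stage:
#' exponential event times with categorical stage and XCI-group hazard
#' ratios, administrative censoring, and optional stage confounding by
#' XCI group (the full-cohort default).
#'
#' @param n number of patients.
#' @param xci_hr hazard ratio applied to both XCI-loss groups.
#' @param group_probs sampling probabilities of the three XCI groups.
#' @param confounded if `TRUE`, stage is drawn from the per-state
#'   distributions of [xci_sim_config()]; if `FALSE`, from a common one.
#' @param baseline_rate,stage_hr,censor_range as in [xci_sim_config()].
#' @return `data.frame` with `time`, `event`, `xci_group`, `stage`.
#' @export
simulate_survival <- function(n, xci_hr = 1.6,
                              group_probs = c(0.5, 0.25, 0.25),
                              confounded = FALSE,
                              baseline_rate = 1e-4,
                              stage_hr = c(III = 4.24, IV = 7.31),
                              censor_range = c(1000, 4000)) {
  cfg <- xci_sim_config(seed = 0L)  # only for its stage_probs default
  g <- sample(XCI_GROUPS, n, TRUE, prob = group_probs)
  if (confounded) {
    stage <- vapply(g, function(s) sample(STAGES, 1, prob = cfg$stage_probs[s, ]), "")
  } else {
    stage <- sample(STAGES, n, TRUE, prob = c(0.72, 0.22, 0.06))
  }
  mult <- ifelse(stage == "III", stage_hr[["III"]],
                 ifelse(stage == "IV", stage_hr[["IV"]], 1)) *
    ifelse(g == "preserved_Xi", 1, xci_hr)
  t_ev <- stats::rexp(n, baseline_rate * mult)
  cens <- stats::runif(n, censor_range[1], censor_range[2])
  data.frame(time = pmin(t_ev, cens), event = t_ev <= cens,
             xci_group = factor(g, XCI_GROUPS),
             stage = factor(stage, STAGES), stringsAsFactors = FALSE)
}

#' Write all cohort artifacts to a directory
#'
#' Emits the six files in the package's file dialects: `manifest.tsv`,
#' `methylation.tsv`, `expression.tsv`, `cnv.seg`, `clinical.csv`,
#' `truth.tsv`, plus one gene list per panel.
#'
#' @param cohort an `xci_cohort`.
#' @param dir output directory (created if needed).
#' @return named character vector of the written paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "xci_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(manifest = file.path(dir, "manifest.tsv"),
             methylation = file.path(dir, "methylation.tsv"),
             expression = file.path(dir, "expression.tsv"),
             seg = file.path(dir, "cnv.seg"),
             clinical = file.path(dir, "clinical.csv"),
             truth = file.path(dir, "truth.tsv"))
  utils::write.table(cohort$manifest, paths["manifest"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_matrix_tsv(round(cohort$methylation, 4), paths["methylation"], "probe_id")
  write_matrix_tsv(round(cohort$expression, 3), paths["expression"], "gene_id")
  seg <- cohort$seg
  names(seg) <- c("Sample", "Chromosome", "Start", "End", "Segment_Mean")
  utils::write.table(seg, paths["seg"], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$clinical, paths["clinical"], sep = ",",
                     quote = FALSE, row.names = FALSE, na = "")
  utils::write.table(cohort$truth, paths["truth"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (p in cohort$panels) {
    pp <- file.path(dir, paste0("panel_", p$name, ".txt"))
    writeLines(c(paste("#", p$name, "gene panel"), p$genes), pp)
    paths[paste0("panel_", p$name)] <- pp
  }
  invisible(paths)
}
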