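#' Read and validate a pipeline configuration
#'
#' YAML with three blocks: `paths` (input/output file locations),
#' `params` (classification thresholds, `k`, chrX arm geometry), and an
#' optional `simulate` block (arguments to [xci_sim_config()]); a root
#' `seed` feeds every source of randomness. Validation happens before
#' any stage runs.
#'
#' @param path YAML file, or a list with the same structure.
#' @return validated config list of class `xci_pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  if (is.null(cfg$seed)) stop_xci("pipeline config requires a root 'seed'")
  cfg$seed <- as.integer(cfg$seed)
  cfg$params <- utils::modifyList(
    list(t_hyper = 0.35, t_hypo = 0.18, t_xist = 6.5, arm_cnv_cut = 0.3,
         k = 3, centromere = 6e7, chrom_length = 1.55e8,
         assignment = "sample"),
    if (is.null(cfg$params)) list() else cfg$params)
  if (is.null(cfg$simulate)) {
    need <- c("methylation", "manifest", "seg", "expression", "clinical")
    miss <- need[!vapply(need, function(nm) !is.null(cfg$paths[[nm]]), TRUE)]
    if (length(miss) > 0) {
      stop_xci("pipeline config: no 'simulate' block, so paths must name: %s",
               paste(miss, collapse = ", "))
    }
  }
  if (is.null(cfg$paths$outdir)) stop_xci("pipeline config requires paths$outdir")
  pp <- unlist(cfg$paths)
  if (anyDuplicated(pp)) stop_xci("pipeline config paths must be distinct")
  class(cfg) <- "xci_pipeline_config"
  cfg
}

#' Run the full analysis pipeline
#'
#' Executes, in order: `simulate` (when configured) writing a synthetic
#' cohort; `classify` producing the XCI calls table; `associate`
#' producing panel-expression and global-methylation comparisons; and
#' `outcomes` producing crosstabs with exact tests, covariate ANOVA,
#' log-rank and stage-adjusted Cox results. All artifacts and a run
#' manifest (seed, config hash, per-stage row counts) land in
#' `paths$outdir`. Identical config + seed reproduces identical outputs.
#'
#' @param config an `xci_pipeline_config` (or path to one).
#' @return the manifest list, invisibly.
#' @export
run_xci_pipeline <- function(config) {
  if (!inherits(config, "xci_pipeline_config")) {
    config <- read_pipeline_config(config)
  }
  outdir <- config$paths$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version = as.character(utils::packageVersion("xciscope")),
                   seed = config$seed,
                   config_hash = config_hash(config),
                   stages = list())

  # -- simulate -----------------------------------------------------------
  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    sim_args$seed <- config$seed
    cohort <- simulate_xci_cohort(do.call(xci_sim_config, sim_args))
    simdir <- file.path(outdir, "cohort")
    paths <- write_cohort(cohort, simdir)
    config$paths$methylation <- paths[["methylation"]]
    config$paths$manifest <- paths[["manifest"]]
    config$paths$seg <- paths[["seg"]]
    config$paths$expression <- paths[["expression"]]
    config$paths$clinical <- paths[["clinical"]]
    manifest$stages$simulate <- list(n_samples = ncol(cohort$methylation),
                                     n_probes = nrow(cohort$methylation),
                                     files = as.list(paths))
  }

  # -- classify -----------------------------------------------------------
  man <- read_manifest(config$paths$manifest)
  meth <- read_methylation(config$paths$methylation, man)
  seg <- read_seg(config$paths$seg)
  expr <- read_expression(config$paths$expression)
  clin <- read_clinical(config$paths$clinical)
  p <- config$params
  fit <- xci_classify(meth, man, clin, seg = seg, expression = expr,
                      k = p$k,
                      thresholds = xci_thresholds(p$t_hyper, p$t_hypo,
                                                  p$t_xist, p$arm_cnv_cut),
                      arms = xci_arm_def(p$centromere, p$chrom_length),
                      assignment = p$assignment)
  calls <- as.data.frame(fit)
  calls_path <- file.path(outdir, "xci_calls.tsv")
  write_calls(calls, calls_path)
  manifest$stages$classify <- list(n_calls = nrow(calls),
                                   groups = as.list(table(calls$xci_group)),
                                   files = list(calls = calls_path))

  # -- associate ----------------------------------------------------------
  panels <- list()
  for (pp in config$paths$panels) {
    loc <- if (grepl("xcta|x_linked", basename(pp), ignore.case = TRUE))
      "X_linked" else "autosomal"
    panels[[length(panels) + 1]] <- read_panel(pp, location = loc)
  }
  if (length(panels) == 0 && !is.null(config$simulate)) {
    panels <- list(read_panel(file.path(outdir, "cohort", "panel_xcta.txt"),
                              "X_linked"),
                   read_panel(file.path(outdir, "cohort",
                                        "panel_cta_autosomal.txt"), "autosomal"))
  }
  assoc_path <- file.path(outdir, "association_tests.tsv")
  if (length(panels) > 0) {
    assoc <- expression_by_group_table(calls, expr, panels, clin)
    # global autosomal island methylation by XCI group
    auto_probes <- select_probes(man, "autosomal", cpg_island_only = TRUE)
    gm <- mean_cpg_methylation(meth, auto_probes, calls$sample_id)
    gcmp <- compare_groups(gm, calls$xci_group)
    assoc <- rbind(assoc,
                   data.frame(panel = "global_autosomal_methylation",
                              grouping = "xci_group", test = gcmp$test,
                              statistic = gcmp$statistic, p_value = gcmp$p_value,
                              band = gcmp$band, n = length(gm),
                              stringsAsFactors = FALSE))
    utils::write.table(assoc, assoc_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    manifest$stages$associate <- list(n_tests = nrow(assoc),
                                      files = list(tests = assoc_path))
  }

  # -- outcomes -----------------------------------------------------------
  clin_m <- clin[match(calls$sample_id, clin$sample_id), ]
  tests <- list()
  for (field in c("histology", "tcga_subtype", "stage", "menopause",
                  "race", "ethnicity", "residual")) {
    ct <- xci_crosstab(clin_m[[field]], calls$xci_group)
    if (ct$degenerate) next
    ft <- fisher_exact_rxc(ct, seed = config$seed)
    tests[[field]] <- data.frame(field = field, test = "fisher_exact",
                                 statistic = NA_real_, p_value = ft$p_value,
                                 n = ct$n, stringsAsFactors = FALSE)
  }
  av <- anova_by_group(clin_m$age, calls$xci_group)
  tests$age <- data.frame(field = "age", test = "anova_oneway",
                          statistic = av$statistic, p_value = av$p_value,
                          n = sum(!is.na(clin_m$age)), stringsAsFactors = FALSE)
  tests_df <- do.call(rbind, tests)
  tests_path <- file.path(outdir, "clinical_tests.tsv")
  utils::write.table(tests_df, tests_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  km <- km_logrank(clin_m$os_time, clin_m$os_event, calls$xci_group)
  cox <- cox_stage_adjusted(clin_m$os_time, clin_m$os_event,
                            calls$xci_group, clin_m$stage)
  cox_path <- file.path(outdir, "cox_os.tsv")
  utils::write.table(cox$terms, cox_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  manifest$stages$outcomes <- list(n_tests = nrow(tests_df),
                                   logrank_p = km$p_value,
                                   files = list(tests = tests_path,
                                                cox = cox_path))

  manifest_path <- file.path(outdir, "run_manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  xci_log("pipeline complete: %d stage(s), manifest at %s",
          length(manifest$stages), manifest_path)
  invisible(manifest)
}

# hash of the analysis-defining parts of the config (seed, params,
# simulation block) -- output locations do not change the analysis
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  x <- unclass(config)
  x$paths <- NULL
  yaml::write_yaml(x[order(names(x))], tmp)
  unname(tools::md5sum(tmp))
}
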