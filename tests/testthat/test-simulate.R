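test_that("generation is deterministic given config and seed", {
  a <- simulate_xci_cohort(xci_sim_config(n_per_cell = 8, seed = 42))
  b <- simulate_xci_cohort(xci_sim_config(n_per_cell = 8, seed = 42))
  expect_identical(a$methylation, b$methylation)
  expect_identical(a$expression, b$expression)
  expect_identical(a$seg, b$seg)
  expect_identical(a$clinical, b$clinical)
  expect_identical(a$truth, b$truth)
})

test_that("changing only the seed changes values but not shapes or ids", {
  a <- simulate_xci_cohort(xci_sim_config(n_per_cell = 8, seed = 1))
  b <- simulate_xci_cohort(xci_sim_config(n_per_cell = 8, seed = 2))
  expect_identical(dim(a$methylation), dim(b$methylation))
  expect_identical(dimnames(a$methylation), dimnames(b$methylation))
  expect_identical(a$truth$sample_id, b$truth$sample_id)
  expect_false(identical(a$methylation, b$methylation))
})

test_that("generated values satisfy their range invariants", {
  co <- small_cohort(seed = 5, n = 10)
  expect_true(all(co$methylation >= 0 & co$methylation <= 1))
  expect_true(all(co$expression >= 0))
  expect_true(all(co$clinical$os_time >= 0))
  # SEG segments non-overlapping per sample+chromosome
  expect_silent(xciscope:::validate_seg(co$seg))
})

test_that("state cells can be emptied and configs are validated", {
  n <- matrix(5, 2, 3, dimnames = list(c("endometrioid", "serous"),
                                       c("preserved_Xi", "Xa_plus", "two_Xa")))
  n[, "two_Xa"] <- 0
  co <- simulate_xci_cohort(xci_sim_config(n_per_cell = n, seed = 9))
  expect_false(any(co$truth$true_xci == "two_Xa"))

  expect_error(xci_sim_config(n_per_cell = 0, seed = 1), "non-empty")
  expect_error(xci_sim_config(seed = NULL), "seed is mandatory")
  expect_error(xci_sim_config(beta_means = c(preserved_Xi = 1.2, Xa_plus = .2,
                                             two_Xa = .1), seed = 1), "in \\(0, 1\\)")
})

test_that("state separation holds across seeds: X methylation and XIST ordering", {
  margins <- vapply(1:10, function(s) {
    co <- simulate_xci_cohort(xci_sim_config(n_per_cell = 60, seed = s))
    x_pr <- select_probes(co$manifest, "chrX")
    mb <- mean_cpg_methylation(co$methylation, x_pr)
    by_state <- tapply(mb, co$truth$true_xci, mean)
    xist <- log2(co$expression["XIST", ] + 1)
    xist_by <- tapply(xist, co$truth$true_xci, mean)
    auto <- mean_cpg_methylation(co$methylation,
                                 select_probes(co$manifest, "autosomal"))
    auto_by <- tapply(auto, co$truth$true_xci, mean)
    expect_lt(xist_by[["two_Xa"]], xist_by[["preserved_Xi"]])
    expect_lte(auto_by[["two_Xa"]], auto_by[["Xa_plus"]])
    expect_lte(auto_by[["Xa_plus"]], auto_by[["preserved_Xi"]])
    by_state[["preserved_Xi"]] - by_state[["two_Xa"]]
  }, 0)
  expect_true(all(margins >= 0.2))
})

test_that("Xi-arm-deletion samples carry matched SEG and methylation signatures", {
  co <- simulate_xci_cohort(xci_sim_config(n_per_cell = 40, seed = 13))
  dels <- co$truth[co$truth$xi_arm_deleted != "none", ]
  expect_gt(nrow(dels), 0)
  expect_true(all(dels$true_xci == "preserved_Xi"))
  for (i in seq_len(nrow(dels))) {
    cnv <- call_arm_cnv(co$seg, dels$sample_id[i])
    meth <- detect_arm_hypomethylation(co$methylation[, dels$sample_id[i]],
                                       co$manifest)
    arm <- dels$xi_arm_deleted[i]
    expect_equal(unname(cnv[arm]), "deleted")
    expect_equal(unname(meth[arm]), "hypo")
    other <- setdiff(c("p", "q"), arm)
    expect_equal(unname(meth[other]), "not_hypo")
    # XIST stays high: these are preserved-Xi tumors
    expect_gt(log2(co$expression["XIST", dels$sample_id[i]] + 1), 5)
  }
})

test_that("truth_table returns one row per sample and round-trips", {
  co <- small_cohort(seed = 2, n = 3)
  tt <- truth_table(co)
  expect_equal(nrow(tt), ncol(co$methylation))
  path <- write_tmp(tt)
  back <- utils::read.delim(path, stringsAsFactors = FALSE)
  expect_equal(back$true_xci, tt$true_xci)

  empty <- co$truth[0, ]
  expect_equal(nrow(truth_table(empty)), 0)
})

test_that("write_cohort emits files the io readers parse back", {
  co <- small_cohort(seed = 21, n = 4)
  dir <- tempfile()
  paths <- write_cohort(co, dir)
  man <- read_manifest(paths[["manifest"]])
  meth <- read_methylation(paths[["methylation"]], man)
  expect_equal(dim(meth), dim(co$methylation))
  expect_equal(meth, co$methylation, tolerance = 1e-3)
  seg <- read_seg(paths[["seg"]])
  expect_equal(nrow(seg), nrow(co$seg))
  clin <- read_clinical(paths[["clinical"]])
  expect_equal(clin$sample_id, co$clinical$sample_id)
  expr <- read_expression(paths[["expression"]])
  expect_equal(expr["XIST", ], co$expression["XIST", ], tolerance = 1e-2)
})
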