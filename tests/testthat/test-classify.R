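test_that("profile_cluster applies the methylation and XIST thresholds", {
  mb <- c(a = 0.45, b = 0.50, c = 0.42)
  xi <- c(a = 8, b = 7.5, c = 8.2)
  p <- profile_cluster(names(mb), mb, xi)
  expect_equal(p$meth_class, "hyper")
  expect_equal(p$xist_class, "high")

  mb2 <- c(a = 0.10, b = 0.10, c = 0.10)
  xi2 <- c(a = 5, b = 5, c = 5)
  p2 <- profile_cluster(names(mb2), mb2, xi2)
  expect_equal(p2$meth_class, "hypo")
  expect_equal(p2$xist_class, "low")

  # the Xa+ signature: partial demethylation with retained XIST
  mb3 <- c(a = 0.25, b = 0.25, c = 0.25)
  xi3 <- c(a = 8.3, b = 8.3, c = 8.3)
  p3 <- profile_cluster(names(mb3), mb3, xi3)
  expect_equal(p3$meth_class, "partial")
  expect_equal(p3$xist_class, "high")

  # XIST unknown when most members lack expression data
  xi4 <- c(a = NA, b = NA, c = 8)
  expect_equal(profile_cluster(names(mb3), mb3, xi4)$xist_class, "unknown")

  expect_error(xci_thresholds(t_hyper = 0.1, t_hypo = 0.2), "below")
})

test_that("arm-level CNV calls use a length-weighted mean with inclusive cutoff", {
  arms <- xci_arm_def(centromere = 6e7, chrom_length = 1.55e8)
  seg1 <- data.frame(sample_id = "s", chrom = "chrX",
                     start = 1, end = 6e7 - 1, seg_mean = -0.8)
  expect_equal(unname(call_arm_cnv(seg1, "s", arms)[["p"]]), "deleted")

  # two equal-length q segments at -0.8 and +0.2: weighted mean -0.3,
  # boundary inclusive -> deleted
  qmid <- (6e7 + 1.55e8) / 2
  seg2 <- data.frame(sample_id = "s", chrom = "chrX",
                     start = c(1, 6e7, qmid + 1),
                     end = c(6e7 - 1, qmid, 1.55e8),
                     seg_mean = c(0, -0.8, 0.2))
  got <- call_arm_cnv(seg2, "s", arms)
  expect_equal(unname(got[["q"]]), "deleted")
  expect_equal(unname(got[["p"]]), "neutral")

  seg3 <- data.frame(sample_id = "s", chrom = "chrX",
                     start = c(1, 6e7), end = c(6e7 - 1, 1.55e8),
                     seg_mean = c(0, 0))
  expect_equal(unname(call_arm_cnv(seg3, "s", arms)), c("neutral", "neutral"))

  # sparse coverage and absent samples fall back to neutral
  seg4 <- data.frame(sample_id = "s", chrom = "chrX",
                     start = 1, end = 1e6, seg_mean = -2)
  expect_equal(unname(call_arm_cnv(seg4, "s", arms)[["p"]]), "neutral")
  expect_equal(unname(call_arm_cnv(seg4, "absent", arms)),
               c("neutral", "neutral"))
})

test_that("arm hypomethylation detection needs 5 probes and flags selective loss", {
  man <- data.frame(probe_id = sprintf("x%02d", 1:20),
                    chrom = "chrX",
                    pos = c(seq(1e6, 5e7, length.out = 10),
                            seq(7e7, 1.5e8, length.out = 10)),
                    cpg_island = TRUE, stringsAsFactors = FALSE)
  b <- c(rep(0.45, 10), rep(0.10, 10))
  names(b) <- man$probe_id
  got <- detect_arm_hypomethylation(b, man)
  expect_equal(unname(got), c("not_hypo", "hypo"))

  both <- rep(0.45, 20); names(both) <- man$probe_id
  expect_equal(unname(detect_arm_hypomethylation(both, man)),
               c("not_hypo", "not_hypo"))

  few <- man[c(1:2, 11:20), ]
  b2 <- b[few$probe_id]
  expect_equal(unname(detect_arm_hypomethylation(b2, few)[["p"]]), "no_probes")
})

test_that("assignment rules map evidence to the three XCI groups", {
  neutral <- data.frame(sample_id = "s", p_arm_cnv = "neutral",
                        q_arm_cnv = "neutral", p_arm_meth = "not_hypo",
                        q_arm_meth = "not_hypo", stringsAsFactors = FALSE)
  prof <- function(meth, xist) {
    structure(list(cluster_id = "c", histology = "serous",
                   member_samples = "s", median_sample_mean_beta = 0.3,
                   meth_class = meth, xist_class = xist),
              class = "xci_cluster_profile")
  }
  expect_equal(assign_status(prof("hyper", "high"), neutral)$xci_group,
               "preserved_Xi")
  expect_equal(assign_status(prof("partial", "high"), neutral)$xci_group,
               "Xa_plus")
  expect_equal(assign_status(prof("hypo", "low"), neutral)$xci_group,
               "two_Xa")

  # whole-X deletion does not change dosage: Xa-only, preserved-equivalent
  whole <- neutral; whole$p_arm_cnv <- "deleted"; whole$q_arm_cnv <- "deleted"
  whole$p_arm_meth <- "hypo"; whole$q_arm_meth <- "hypo"
  res <- assign_status(prof("hypo", "low"), whole)
  expect_equal(res$xci_group, "preserved_Xi")
  expect_match(res$flags, "whole_X_deletion")

  # selective q hypomethylation + q deletion: Xi arm loss, overridden
  qdel <- neutral; qdel$q_arm_cnv <- "deleted"; qdel$q_arm_meth <- "hypo"
  res2 <- assign_status(prof("partial", "high"), qdel)
  expect_equal(res2$xci_group, "preserved_Xi")
  expect_true(res2$override_applied)

  # selective hypomethylation without a matching deletion is not overridden
  qhypo <- neutral; qhypo$q_arm_meth <- "hypo"
  expect_false(assign_status(prof("partial", "high"), qhypo)$override_applied)

  # conflicts resolved by methylation class, flagged
  res3 <- assign_status(prof("hypo", "high"), neutral)
  expect_equal(res3$xci_group, "two_Xa")
  expect_match(res3$flags, "conflict")
  res4 <- assign_status(prof("hyper", "low"), neutral)
  expect_equal(res4$xci_group, "preserved_Xi")
  expect_match(res4$flags, "conflict")

  # no XIST data: classified by methylation + CNV, low confidence
  res5 <- assign_status(prof("partial", "unknown"), neutral)
  expect_equal(res5$xci_group, "Xa_plus")
  expect_match(res5$flags, "low_confidence")
})

test_that("classify recovers truth on a small default cohort in both modes", {
  co <- simulate_xci_cohort(xci_sim_config(n_per_cell = 20, seed = 30))
  fit <- xci_classify(co$methylation, co$manifest, co$clinical,
                      seg = co$seg, expression = co$expression)
  calls <- as.data.frame(fit)
  tr <- co$truth[match(calls$sample_id, co$truth$sample_id), ]
  expect_gte(mean(calls$xci_group == tr$true_xci), 0.95)

  # cluster-level mode on a deletion-free cohort matches the same truth
  co2 <- simulate_xci_cohort(xci_sim_config(n_per_cell = 20,
                                            xi_arm_deletion_fraction = 0,
                                            seed = 31))
  fit2 <- xci_classify(co2$methylation, co2$manifest, co2$clinical,
                       seg = co2$seg, expression = co2$expression,
                       assignment = "cluster")
  calls2 <- as.data.frame(fit2)
  tr2 <- co2$truth[match(calls2$sample_id, co2$truth$sample_id), ]
  expect_gte(mean(calls2$xci_group == tr2$true_xci), 0.95)
})

test_that("calls are invariant to sample and probe permutations", {
  co <- small_cohort(seed = 17, n = 8)
  fit1 <- xci_classify(co$methylation, co$manifest, co$clinical,
                       seg = co$seg, expression = co$expression)
  set.seed(2)
  perm_m <- co$methylation[sample(nrow(co$methylation)),
                           sample(ncol(co$methylation))]
  perm_clin <- co$clinical[sample(nrow(co$clinical)), ]
  fit2 <- xci_classify(perm_m, co$manifest, perm_clin,
                       seg = co$seg, expression = co$expression)
  expect_equal(as.data.frame(fit1), as.data.frame(fit2))
})

test_that("every call is re-derivable from its stored evidence", {
  co <- small_cohort(seed = 23, n = 10)
  calls <- as.data.frame(xci_classify(co$methylation, co$manifest, co$clinical,
                                      seg = co$seg, expression = co$expression))
  for (i in seq_len(nrow(calls))) {
    re <- xciscope:::assign_one(calls$meth_class[i], calls$xist_class[i],
                                calls$p_arm_cnv[i], calls$q_arm_cnv[i],
                                calls$p_arm_meth[i], calls$q_arm_meth[i])
    expect_equal(re$xci_group, calls$xci_group[i], info = calls$sample_id[i])
    expect_equal(re$override_applied, calls$override_applied[i])
  }
})

test_that("uniformly decreasing a sample's X betas never raises its meth class", {
  co <- small_cohort(seed = 19, n = 6)
  rank_of <- c(hypo = 1, partial = 2, hyper = 3)
  xp <- select_probes(co$manifest, "chrX")
  sid <- co$truth$sample_id[co$truth$true_xci == "Xa_plus"][1]
  base_calls <- as.data.frame(xci_classify(co$methylation, co$manifest,
                                           co$clinical, seg = co$seg,
                                           expression = co$expression))
  base <- rank_of[base_calls$meth_class[base_calls$sample_id == sid]]
  for (shrink in c(0.8, 0.5, 0.2)) {
    m <- co$methylation
    m[xp, sid] <- m[xp, sid] * shrink
    calls <- as.data.frame(xci_classify(m, co$manifest, co$clinical,
                                        seg = co$seg, expression = co$expression))
    got <- rank_of[calls$meth_class[calls$sample_id == sid]]
    expect_lte(got, base)
    base <- got
  }
})

test_that("samples without XIST data are classified and flagged", {
  co <- small_cohort(seed = 27, n = 8)
  fit <- xci_classify(co$methylation, co$manifest, co$clinical, seg = co$seg,
                      expression = NULL)
  calls <- as.data.frame(fit)
  expect_true(all(calls$xist_class == "unknown"))
  tr <- co$truth[match(calls$sample_id, co$truth$sample_id), ]
  # methylation + CNV alone still recover the truth states
  expect_gte(mean(calls$xci_group == tr$true_xci), 0.9)
})

test_that("a stratum smaller than k is rejected with advice", {
  co <- small_cohort(seed = 3, n = 1)
  expect_error(xci_classify(co$methylation, co$manifest, co$clinical,
                            seg = co$seg, expression = co$expression, k = 5),
               "reduce k")
})

test_that("fit object methods print and summarize", {
  co <- small_cohort(seed = 4, n = 5)
  fit <- xci_classify(co$methylation, co$manifest, co$clinical,
                      seg = co$seg, expression = co$expression)
  expect_output(print(fit), "XCI status classification")
  s <- summary(fit)
  expect_s3_class(s, "summary.xci_fit")
  expect_equal(nrow(s$clusters), 6)   # 3 clusters x 2 histologies
  expect_output(print(s), "Cluster profiles")
})
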