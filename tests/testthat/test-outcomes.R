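test_that("crosstab reproduces counts and column percentages", {
  counts <- histology_xci_counts()
  lab <- labels_from_counts(counts)
  # columns = histology here, so column percentages are within-histology
  ct <- xci_crosstab(lab$rows, lab$cols)
  expect_equal(ct$counts[rownames(counts), colnames(counts)],
               unclass(counts))
  expect_equal(round(ct$col_pct["preserved_Xi", "endometrioid"], 1), 84.1)
  expect_equal(round(ct$col_pct["preserved_Xi", "serous"], 1), 51.6)
  expect_equal(round(ct$col_pct["Xa_plus", "serous"], 1), 34.7)
  expect_equal(ct$n, 371)

  expect_error(xci_crosstab(rnorm(5), rep("a", 5)), "continuous")

  degen <- xci_crosstab(rep("only", 4), rep(c("g1", "g2"), 2))
  expect_true(degen$degenerate)
})

test_that("missing values are dropped with the effective N reported", {
  f <- c("x", "y", NA, "x")
  g <- c("g1", "g1", "g2", NA)
  ct <- xci_crosstab(f, g)
  expect_equal(ct$n, 2)
})

test_that("balanced and degenerate contingency tables behave by convention", {
  expect_equal(fisher_exact_rxc(matrix(1, 2, 2))$p_value, 1)
  degen <- fisher_exact_rxc(rbind(c(0, 0), c(3, 4)))
  expect_true(degen$degenerate)
  expect_equal(degen$p_value, 1)
  expect_error(fisher_exact_rxc(rbind(c(-1, 2), c(3, 4))), "negative")
  expect_error(fisher_exact_rxc(matrix(1, 1, 2)), "2 x 2")
})

test_that("exact test is invariant under permutation and transposition", {
  set.seed(5)
  for (rep in 1:10) {
    x <- matrix(rpois(6, 4), 2, 3)
    if (any(rowSums(x) == 0) || any(colSums(x) == 0)) next
    p <- fisher_exact_rxc(x)$p_value
    expect_gt(p, 0); expect_lte(p, 1)
    expect_equal(fisher_exact_rxc(x[, c(2, 3, 1)])$p_value, p)
    expect_equal(fisher_exact_rxc(x[c(2, 1), ])$p_value, p)
    expect_equal(fisher_exact_rxc(t(x))$p_value, p)
  }
})

test_that("Monte-Carlo fallback engages on huge tables and is seeded", {
  x <- matrix(c(5000, 4800, 5100, 4900, 5050, 4950), 2, 3)
  got <- fisher_exact_rxc(x, mc_threshold = 10, B = 1e4, seed = 99)
  expect_equal(got$method, "monte_carlo")
  again <- fisher_exact_rxc(x, mc_threshold = 10, B = 1e4, seed = 99)
  expect_equal(got$p_value, again$p_value)
  expect_error(fisher_exact_rxc(x, mc_threshold = 10, B = 1e4), "seed")
})

test_that("ANOVA by group detects shifts and degrades gracefully", {
  set.seed(8)
  v <- c(rnorm(30), rnorm(30, 5), rnorm(30))
  g <- rep(letters[1:3], each = 30)
  res <- anova_by_group(v, g)
  expect_lt(res$p_value, 0.001)

  # constant covariate: degenerate, p = 1
  const <- anova_by_group(rep(2, 30), rep(letters[1:3], 10))
  expect_true(const$degenerate)
  expect_equal(const$p_value, 1)

  expect_error(anova_by_group(rnorm(10), rep("a", 10)), "at least 2")
})

test_that("Kaplan-Meier curves start at 1 and never increase", {
  set.seed(10)
  km <- km_logrank(rexp(80, 0.01), rbinom(80, 1, 0.7),
                   rep(c("a", "b"), 40))
  expect_true(all(km$curves$survival <= 1))
  for (g in unique(km$curves$group)) {
    s <- km$curves$survival[km$curves$group == g]
    expect_true(all(diff(s) <= 1e-12))
  }
  s0 <- summary(km$survfit, times = 0)
  expect_true(all(s0$surv == 1))
})

test_that("log-rank separates different hazards and not identical groups", {
  set.seed(20)
  t1 <- rexp(200, 0.003); t2 <- rexp(200, 0.009)
  cens <- runif(400, 100, 2000)
  time <- pmin(c(t1, t2), cens); ev <- c(t1, t2) <= cens
  km <- km_logrank(time, ev, rep(c("slow", "fast"), each = 200))
  expect_lt(km$p_value, 0.001)

  # exchangeable groups: p should be comfortably non-significant
  set.seed(21)
  t0 <- rexp(300, 0.005)
  km0 <- km_logrank(t0, rep(TRUE, 300), sample(rep(c("a", "b"), 150)))
  expect_gt(km0$p_value, 0.05)

  expect_error(km_logrank(c(1, 2, 3, 4), c(0, 0, 0, 0), c("a", "a", "b", "b")),
               "no events")
})

test_that("stage-adjusted Cox recovers hazard ratios and errors without events", {
  set.seed(33)
  d <- simulate_survival(800, xci_hr = 1.6)
  cox <- cox_stage_adjusted(d$time, d$event, d$xci_group, d$stage)
  expect_equal(nrow(cox$terms), 4)
  expect_true(all(cox$terms$hr > 0))
  expect_true(all(cox$terms$lo <= cox$terms$hr & cox$terms$hr <= cox$terms$hi))
  xci_terms <- cox$terms[grep("xci_group", cox$terms$term), ]
  expect_true(all(xci_terms$hr > 0.9 & xci_terms$hr < 2.9))

  expect_error(cox_stage_adjusted(c(1, 2, 3), c(0, 0, 0),
                                  c("preserved_Xi", "Xa_plus", "two_Xa"),
                                  c("I_II", "III", "IV")),
               "no events")
})

test_that("Cox bias shrinks as the cohort grows", {
  bias_at <- function(n, reps, seed0) {
    lhr <- vapply(seq_len(reps), function(i) {
      set.seed(seed0 + i)
      d <- simulate_survival(n, xci_hr = 1.6)
      fit <- cox_stage_adjusted(d$time, d$event, d$xci_group, d$stage)
      mean(log(fit$terms$hr[grep("xci_group", fit$terms$term)]))
    }, 0)
    abs(mean(lhr) - log(1.6))
  }
  expect_lt(bias_at(1200, 40, 500), 0.06)
  expect_lt(bias_at(150, 40, 900), 0.30)
})

test_that("confounded stage attenuates the marginal XCI effect", {
  set.seed(77)
  d <- simulate_survival(3000, xci_hr = 1.6, confounded = TRUE)
  # marginal (unadjusted) two-group Cox inflates the loss-of-XCI effect
  loss <- d$xci_group != "preserved_Xi"
  marg <- survival::coxph(survival::Surv(time, event) ~ loss, data = d)
  adj <- cox_stage_adjusted(d$time, d$event, d$xci_group, d$stage)
  adj_mean <- mean(log(adj$terms$hr[grep("xci_group", adj$terms$term)]))
  expect_gt(unname(coef(marg)), adj_mean)
})
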