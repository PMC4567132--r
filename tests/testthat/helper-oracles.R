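# Independent oracles and fixture builders used across the test files.

# Naive O(n^3) agglomerative complete-linkage clustering, written directly
# from the definition: repeatedly merge the two clusters whose maximum
# pairwise member distance is smallest, until k clusters remain.
naive_complete_linkage <- function(x, k) {
  n <- nrow(x)
  d <- as.matrix(dist(x))
  clusters <- as.list(seq_len(n))
  while (length(clusters) > k) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) {
      for (j in seq_len(i - 1)) {
        h <- max(d[clusters[[i]], clusters[[j]]])
        if (h < best[1]) best <- c(h, i, j)
      }
    }
    i <- best[2]; j <- best[3]
    clusters[[j]] <- c(clusters[[j]], clusters[[i]])
    clusters[[i]] <- NULL
  }
  lab <- integer(n)
  for (ci in seq_along(clusters)) lab[clusters[[ci]]] <- ci
  lab
}

# Exhaustive generalized-Fisher oracle: enumerate every table with the
# observed margins, sum the multivariate hypergeometric probabilities of
# tables no more probable than the observed one.
fisher_enumeration_oracle <- function(x) {
  x <- as.matrix(x)
  rs <- rowSums(x); cs <- colSums(x); n <- sum(x)
  log_prob <- function(tab) {
    sum(lfactorial(rs)) + sum(lfactorial(cs)) - lfactorial(n) -
      sum(lfactorial(tab))
  }
  lp_obs <- log_prob(x)
  total <- 0
  # recursive enumeration over rows; each row is a composition of its
  # margin constrained by the remaining column budget
  recurse <- function(row_idx, col_left, acc_lp) {
    if (row_idx == nrow(x)) {
      # last row is forced
      if (any(col_left < 0)) return()
      lp <- acc_lp - sum(lfactorial(col_left))
      if (lp <= lp_obs + 1e-7) total <<- total + exp(lp)
      return()
    }
    for (comp in compositions(rs[row_idx], length(cs))) {
      if (all(comp <= col_left)) {
        recurse(row_idx + 1, col_left - comp, acc_lp - sum(lfactorial(comp)))
      }
    }
  }
  base_lp <- sum(lfactorial(rs)) + sum(lfactorial(cs)) - lfactorial(n)
  recurse(1, cs, base_lp)
  min(total, 1)
}

# all ways to write total as an ordered sum of `parts` nonnegative
# integers (memoised: reused heavily by the enumeration sweeps)
.comp_cache <- new.env(parent = emptyenv())
compositions <- function(total, parts) {
  key <- paste(total, parts)
  if (!is.null(.comp_cache[[key]])) return(.comp_cache[[key]])
  out <- if (parts == 1) {
    list(total)
  } else {
    acc <- list()
    for (v in 0:total) {
      for (rest in compositions(total - v, parts - 1)) {
        acc[[length(acc) + 1]] <- c(v, rest)
      }
    }
    acc
  }
  .comp_cache[[key]] <- out
  out
}

adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(sum(tab), 2)
  maxidx <- (sum_a + sum_b) / 2
  if (maxidx == expected) return(1)
  (sum_ij - expected) / (maxidx - expected)
}

# minimal manifest: nx chrX island, nxn chrX non-island, na autosomal island
tiny_manifest <- function(nx = 3, nxn = 2, na = 4) {
  data.frame(
    probe_id = sprintf("p%02d", seq_len(nx + nxn + na)),
    chrom = c(rep("chrX", nx + nxn), rep("chr2", na)),
    pos = c(seq(1e6, 9e7, length.out = nx + nxn), seq(1e6, 5e7, length.out = na)),
    cpg_island = rep(c(TRUE, FALSE, TRUE), c(nx, nxn, na)),
    stringsAsFactors = FALSE)
}

# write a data.frame as TSV/CSV and return the path
write_tmp <- function(df, sep = "\t", ext = ".tsv") {
  path <- tempfile(fileext = ext)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE,
                     na = "")
  path
}

small_cohort <- function(seed = 11, n = 12) {
  simulate_xci_cohort(xci_sim_config(n_per_cell = n, seed = seed))
}
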