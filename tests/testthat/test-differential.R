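test_that("paired t matches the closed form on the toy example", {
  res <- paired_t_test(c(1, 2, 3), c(2, 4, 6))
  expect_equal(res$t_stat, sqrt(12), tolerance = 1e-4)   # 3.4641
  expect_equal(res$df, 2L)
  expect_equal(res$p_raw, 0.07418, tolerance = 1e-3)
  # cross-check against the reference implementation
  ref <- t.test(c(2, 4, 6), c(1, 2, 3), paired = TRUE)
  expect_equal(res$t_stat, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(res$p_raw, ref$p.value, tolerance = 1e-12)
})

test_that("paired t handles degenerate and insufficient inputs per contract", {
  deg <- paired_t_test(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_true(deg$degenerate)
  expect_equal(deg$p_raw, 1)
  expect_equal(deg$t_stat, 0)
  expect_error(paired_t_test(c(1, 2), c(2, 3)), "insufficient")
  # missing values drop whole pairs
  res <- paired_t_test(c(1, 2, 3, NA), c(2, 4, 6, 5))
  expect_equal(res$n_pairs, 3L)
})

test_that("BH adjustment equals the hand-applied step-up formula", {
  # independent oracle: sort ascending, p*(m/i), cumulative min from the top
  bh_oracle <- function(p) {
    m <- length(p); o <- order(p)
    adj <- rev(cummin(rev(p[o] * m / seq_len(m))))
    pmin(1, adj)[order(o)]
  }
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(c(0.005, 0.5)), c(0.01, 0.5))
  expect_equal(bh_adjust(0.3), 0.3)
  set.seed(10)
  for (i in 1:20) {
    p <- runif(sample(3:30, 1))
    expect_equal(bh_adjust(p), bh_oracle(p))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("BH is permutation-equivariant and never below the raw p", {
  set.seed(11)
  p <- runif(17)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p))
  perm <- sample(17)
  expect_equal(bh_adjust(p[perm]), adj[perm])
})

test_that("the significance gate combines adjusted p and fold change", {
  rec <- data.frame(peptide_id = c("a", "b", "c", "d"),
                    accession = c("X", "X", "Y", "Z"),
                    ratio = c(3, 0.4, 5, 1.5),
                    p_adj = c(0.01, 0.01, 0.06, 0.01))
  rec$fold_change <- pmax(rec$ratio, 1 / rec$ratio)
  rec$direction <- ifelse(rec$ratio > 1, "up", "down")
  out <- classify_differential(rec)
  expect_equal(out$significant, c(TRUE, TRUE, FALSE, FALSE))
  s <- attr(out, "summary")
  expect_equal(s$n_significant, 2)
  expect_equal(s$n_up, 1); expect_equal(s$n_down, 1)
  expect_equal(s$n_proteins_significant, 1)
})

test_that("swapping phase labels inverts ratios and flips direction, not evidence", {
  set.seed(12)
  ctrl <- matrix(exp(rnorm(44)), 4, 11)
  trt <- matrix(exp(rnorm(44, 0.5)), 4, 11)
  a <- run_differential(paired_matrix(ctrl, trt))
  b <- run_differential(paired_matrix(trt, ctrl))
  expect_equal(b$ratio, 1 / a$ratio, tolerance = 1e-12)
  expect_equal(b$fold_change, a$fold_change, tolerance = 1e-12)
  expect_equal(abs(b$t_stat), abs(a$t_stat), tolerance = 1e-12)
  expect_equal(b$p_raw, a$p_raw, tolerance = 1e-12)
  expect_equal(b$direction, ifelse(a$direction == "up", "down", "up"))
})

test_that("KS comparison of length distributions matches its contract cases", {
  same <- compare_length_distributions(c(10, 12, 14), c(10, 12, 14))
  expect_equal(same$D, 0)
  expect_equal(same$p, 1)
  disjoint <- compare_length_distributions(c(10, 12, 14), c(20, 22, 24))
  expect_equal(disjoint$D, 1)
  expect_error(compare_length_distributions(numeric(0), 1:3), "non-empty")
})

test_that("replicate Spearman matrix is symmetric with unit diagonal and rank logic", {
  v <- cbind(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4), c = c(4, 3, 2, 1))
  mat <- toy_matrix(cbind(v, v[, 1]), n_subjects = 2)
  rho <- replicate_correlation(mat)
  expect_equal(unname(diag(rho)), rep(1, 4))
  expect_equal(rho, t(rho))
  expect_equal(unname(rho[1, 2]), 1)
  expect_equal(unname(rho[1, 3]), -1)
  # fewer than 3 shared values -> undefined
  v2 <- cbind(c(1, 2, NA, NA), c(NA, NA, 1, 2), c(1, 2, 3, 4), c(1, 2, 3, 4))
  rho2 <- replicate_correlation(toy_matrix(v2, n_subjects = 2))
  expect_true(is.na(rho2[1, 2]))
})

test_that("hierarchical clustering separates well-split groups and merges duplicates", {
  set.seed(13)
  g1 <- matrix(rnorm(30, 0, 0.1), 10, 3)
  g2 <- matrix(rnorm(30, 10, 0.1), 10, 3)
  vals <- cbind(g1, g2)
  colnames(vals) <- paste0("s", 1:6)
  cl <- cluster_samples(vals, k = 2)
  expect_equal(length(unique(cl$clusters[1:3])), 1L)
  expect_equal(length(unique(cl$clusters[4:6])), 1L)
  expect_false(cl$clusters[1] == cl$clusters[4])
  # duplicated sample merges at height zero
  dup <- cbind(vals, s7 = vals[, 1])
  hc <- cluster_samples(dup, k = 2)$hclust
  expect_equal(min(hc$height), 0)
  # single sample: single leaf
  single <- cluster_samples(vals[, 1, drop = FALSE], k = 2)
  expect_equal(unname(single$clusters), 1L)
  vals[1, 1] <- NA
  expect_error(cluster_samples(vals), "impute")
})

test_that("over-representation matches the exact hypergeometric oracle", {
  # oracle: direct sum of the hypergeometric pmf
  universe <- paste0("u", 1:20)
  term <- universe[1:5]
  query <- c(universe[1:4], universe[10])
  res <- enrich_over_representation(query, list(T1 = term), universe,
                                    min_hits = 4, min_fold = 1)
  p_oracle <- sum(sapply(4:5, function(k)
    choose(5, k) * choose(15, 5 - k) / choose(20, 5)))
  expect_equal(res$p[res$term_id == "T1"], p_oracle, tolerance = 1e-12)
  expect_true(res$retained[res$term_id == "T1"])
  expect_equal(res$fold_enrichment[1], (4 / 5) / (5 / 20))
})

test_that("over-representation filters by hits and fold enrichment", {
  universe <- paste0("u", 1:20)
  query <- universe[1:5]
  sets <- list(small = universe[c(1:3, 15)],   # 3 hits -> excluded
               whole = universe)               # fold 1 -> excluded
  res <- enrich_over_representation(query, sets, universe)
  expect_false(any(res$retained))
  expect_equal(res$fold_enrichment[res$term_id == "whole"], 1)
  expect_error(enrich_over_representation(character(0), sets, universe),
               "empty")
})

test_that("the advisory normality screen reports per-peptide KS p-values", {
  set.seed(14)
  ctrl <- matrix(exp(rnorm(22)), 2, 11)
  trt <- ctrl * matrix(exp(rnorm(22, 0, 0.2)), 2, 11)
  scr <- normality_screen(paired_matrix(ctrl, trt))
  expect_equal(nrow(scr), 2)
  expect_true(all(scr$ks_p >= 0 & scr$ks_p <= 1))
})
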