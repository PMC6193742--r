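test_that("score standardization maps each scope onto [0, 1]", {
  v <- cbind(c(0.2, 0.5, 0.8), c(1, 3, 2))
  m <- gene_lineage_matrix(v, mode = "continuous", g0 = 3)
  w <- standardize_scores(m, "within_lineage")
  expect_equal(unname(w$values[, 1]), c(0, 0.5, 1))
  expect_equal(unname(w$values[, 2]), c(0, 1, 0.5))

  g <- standardize_scores(m, "global")
  expect_equal(range(g$values), c(0, 1))
  expect_equal(unname(g$values[, 1]), (c(0.2, 0.5, 0.8) - 0.2) / 2.8)

  already <- gene_lineage_matrix(cbind(c(0, 0.4, 1), c(0, 1, 0.3)),
                                 mode = "continuous", g0 = 3)
  expect_equal(standardize_scores(already, "within_lineage")$values,
               already$values)

  flat <- gene_lineage_matrix(cbind(c(1, 1, 1), c(0, 1, 2)),
                              lineage_ids = c("flat", "ok"),
                              mode = "continuous", g0 = 3)
  expect_error(standardize_scores(flat), "flat")
})

test_that("the dispersion statistic matches hand computation over the full universe", {
  y4 <- yeast_nystatin_matrix(4)
  expect_equal(chisq_stat(y4), 14.4)  # totals 11,7,1,1 against e = 5

  # implicit zero genes enter the statistic: same totals, larger universe
  y6604 <- yeast_nystatin_matrix(6604)
  e <- 20 / 6604
  expect_equal(chisq_stat(y6604),
               (121 + 49 + 1 + 1) / e - 20, tolerance = 1e-9)

  balanced <- gene_lineage_matrix(matrix(1, 5, 3), g0 = 5)
  expect_equal(chisq_stat(balanced), 0)
  expect_error(chisq_stat(gene_lineage_matrix(matrix(0, 2, 2), g0 = 4)),
               "zero")
})

test_that("a single lineage is invariant under permutation, so p = 1", {
  one <- gene_lineage_matrix(matrix(c(1, 1, 0, 0), 4, 1), g0 = 10)
  res <- permutation_pvalue(one, n_permutations = 200, seed = 5)
  expect_equal(res$p_value, 1)
  expect_equal(res$null_sd, 0)
})

test_that("permutation results are reproducible under a fixed seed", {
  m <- random_binary_matrix(g0 = 40, k = 4, a = 6, seed = 2)
  a <- c_chisq(m, n_permutations = 300, seed = 123)
  b <- c_chisq(m, n_permutations = 300, seed = 123)
  expect_identical(a, b)
  # and the call leaves the session RNG untouched
  set.seed(99); before <- .Random.seed
  invisible(permutation_null(m, 50, seed = 7))
  expect_identical(.Random.seed, before)
})

test_that("null moments: multinomial-like for sparse lineages, finite-population otherwise", {
  # one adapted gene per lineage (yeast design): permutation equals
  # independent multinomial placement, so the null mean is the analytic
  # chi-square df
  y4 <- yeast_nystatin_matrix(4)
  null <- permutation_null(y4, 20000, seed = 31)
  expect_equal(mean(null$stats), 3, tolerance = 0.03)

  # fixed within-lineage totals give E[chi2] = g0 - a (not df = g0 - 1);
  # the deviation from the analytic df is large when lineages adapt a large
  # fraction of the universe and fades as that fraction shrinks
  heavy <- random_binary_matrix(g0 = 20, k = 10, a = 10, seed = 4)
  nh <- permutation_null(heavy, 4000, seed = 8)
  expect_equal(mean(nh$stats), 20 - 10, tolerance = 0.05)
  expect_gt(abs(mean(nh$stats) - 19) / 19, 0.4)

  light <- random_binary_matrix(g0 = 40, k = 40, a = 2, seed = 4)
  nl <- permutation_null(light, 4000, seed = 8)
  expect_lt(abs(mean(nl$stats) - 39) / 39, 0.05)
})

test_that("permutation p-values reproduce the yeast tests", {
  y4 <- yeast_nystatin_matrix(4)
  res <- permutation_pvalue(y4, n_permutations = 40000, seed = 17)
  expect_equal(res$p_value, 0.002, tolerance = 0.5)  # stochastic target
  expect_lt(res$p_value, 0.004)
  expect_gt(res$p_value, 0.0008)

  y <- yeast_nystatin_matrix(6604)
  res2 <- permutation_pvalue(y, n_permutations = 20000, seed = 17)
  expect_equal(res2$p_value, 0)
})

test_that("p-values are approximately uniform under a true null", {
  ps <- vapply(1:200, function(i) {
    m <- random_binary_matrix(g0 = 50, k = 3, a = 5, seed = 5000 + i)
    permutation_pvalue(m, n_permutations = 400, seed = i)$p_value
  }, numeric(1))
  frac <- mean(ps <= 0.05)
  expect_gte(frac, 0.02)
  expect_lte(frac, 0.10)
})

test_that("C_chisq is centred at zero for data at the null expectation", {
  v <- matrix(0, 16, 2); v[1:4, 1] <- 1; v[c(1, 5:7), 2] <- 1  # a_s = E[a_s]
  m0 <- gene_lineage_matrix(v, g0 = 16)
  res <- c_chisq(m0, n_permutations = 10000, seed = 21)
  expect_lt(abs(res$c_score), 0.3)
})

test_that("C_chisq agrees with C_hyper pair by pair on the yeast data", {
  y4 <- yeast_nystatin_matrix(4)
  pick <- list(c(1, 2), c(1, 12), c(12, 19))  # shared, distinct, distinct
  for (pr in pick) {
    sub <- gene_lineage_matrix(y4$values[, pr], y4$gene_ids,
                               c("a", "b"), g0 = 4)
    obs <- chisq_stat(sub)
    null <- permutation_null(sub, 20000, seed = 41)
    cc <- (obs - mean(null$stats)) / sd(null$stats)
    ch <- c_hyper(pairwise_counts(sub, 1, 2))
    expect_equal(cc, ch, tolerance = 0.2)
  }
})

test_that("binary and continuous chi-square formulations coincide on 0/1 data", {
  m <- random_binary_matrix(g0 = 30, k = 3, a = 5, seed = 6)
  cont <- gene_lineage_matrix(m$values, g0 = m$g0, mode = "continuous")
  expect_identical(chisq_stat(m), chisq_stat(cont))
  expect_identical(c_chisq(m, 200, seed = 3)$c_score,
                   c_chisq(cont, 200, seed = 3)$c_score)
})

test_that("inclusive vs strict tie handling and the (b+1)/(B+1) estimator", {
  one_gene <- gene_lineage_matrix(matrix(1, 1, 2), g0 = 1)
  # with g0 = 1 every permutation is a tie: inclusive p = 1, strict p = 0
  expect_equal(permutation_pvalue(one_gene, 100, seed = 1)$p_value, 1)
  expect_equal(permutation_pvalue(one_gene, 100, seed = 1,
                                  strict_greater = TRUE)$p_value, 0)
  y <- yeast_nystatin_matrix(6604)
  res <- permutation_pvalue(y, 500, seed = 2, add_one = TRUE)
  expect_equal(res$p_value, 1 / 501)
})
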