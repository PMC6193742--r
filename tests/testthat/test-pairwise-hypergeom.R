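test_that("expected overlap follows a_x * a_y / g0", {
  expect_equal(expected_overlap(pairwise_counts_from(50, 121, 5, 9891)),
               50 * 121 / 9891)
  expect_equal(expected_overlap(pairwise_counts_from(0, 40, 0, 100)), 0)
  expect_equal(expected_overlap(pairwise_counts_from(100, 40, 40, 100)), 40)
})

test_that("C_hyper matches hand-evaluated and published values", {
  expect_equal(c_hyper(pairwise_counts_from(1, 1, 1, 4)),
               (1 - 0.25) / sqrt(3 / 16), tolerance = 1e-12)
  conifer <- c_hyper(conifer_counts("mcmt"))
  expect_equal(conifer, 5.6597, tolerance = 1e-4)
  # the published value is 5.6 at one decimal (truncated)
  expect_lt(abs(conifer - 5.6), 0.1)
  # overlap exactly at expectation scores zero
  expect_equal(c_hyper(pairwise_counts_from(4, 4, 1, 16)), 0)
  # degenerate nulls are flagged, not silently numeric
  expect_warning(z <- c_hyper(pairwise_counts_from(0, 5, 0, 10)), "undefined")
  expect_true(is.na(z))
  expect_warning(c_hyper(pairwise_counts_from(10, 5, 5, 10)), "undefined")
})

test_that("hypergeometric p-values match the published conifer contrasts", {
  expect_equal(signif(hypergeom_pvalue(conifer_counts("mcmt")), 2), 0.00034)
  expect_equal(hypergeom_pvalue(conifer_counts("ahm_spruce_vs_pine_mcmt")),
               0.11, tolerance = 0.005)
  expect_equal(hypergeom_pvalue(conifer_counts("ahm_pine_vs_spruce_mcmt")), 1)
  expect_error(hypergeom_pvalue(pairwise_counts_from(2.5, 4, 1, 10)),
               "integer")
})

test_that("zero observed overlap always gives p = 1", {
  for (seed in 1:10) {
    cfg <- adaptrepeat:::with_seed(seed, {
      g0 <- sample(5:50, 1)
      c(sample.int(g0 %/% 2, 1), sample.int(g0 %/% 2, 1), g0)
    })
    cc <- pairwise_counts_from(cfg[1], cfg[2], 0, cfg[3])
    expect_equal(hypergeom_pvalue(cc), 1)
  }
})

test_that("exhaustive enumeration reproduces the tail p and the C_hyper moments", {
  # draw every possible a_x-subset of a g0 <= 12 universe against a fixed
  # a_y-set; the overlap distribution so enumerated is an oracle for both
  # the p-value and the mean/SD used by C_hyper
  cases <- list(c(g0 = 12, ax = 5, ay = 4), c(g0 = 10, ax = 3, ay = 7),
                c(g0 = 8, ax = 4, ay = 4))
  for (cs in cases) {
    g0 <- unname(cs["g0"]); ax <- unname(cs["ax"]); ay <- unname(cs["ay"])
    yset <- seq_len(ay)
    overlaps <- utils::combn(g0, ax, function(s) sum(s %in% yset))
    for (as_obs in 0:min(ax, ay)) {
      p_enum <- mean(overlaps >= as_obs)
      expect_equal(hypergeom_pvalue(pairwise_counts_from(ax, ay, as_obs, g0)),
                   p_enum, tolerance = 1e-13)
    }
    mu <- mean(overlaps); sdev <- sqrt(mean((overlaps - mu)^2))
    expect_equal(mu, ax * ay / g0, tolerance = 1e-13)
    expect_equal(sdev,
                 sqrt(ax * ay * (g0 - ax) * (g0 - ay) / (g0^2 * (g0 - 1))),
                 tolerance = 1e-13)
    # C_hyper is exactly the z-score under the enumerated distribution
    expect_equal(c_hyper(pairwise_counts_from(ax, ay, 2, g0)),
                 (2 - mu) / sdev, tolerance = 1e-12)
  }
})

test_that("Monte-Carlo draws match the analytic mean, SD and tail", {
  g0 <- 30; ax <- 8; ay <- 12; n <- 1e5
  yset <- seq_len(ay)
  draws <- adaptrepeat:::with_seed(77,
    replicate(n, sum(sample.int(g0, ax) %in% yset)))
  mu <- ax * ay / g0
  sdev <- sqrt(ax * ay * (g0 - ax) * (g0 - ay) / (g0^2 * (g0 - 1)))
  expect_lt(abs(mean(draws) - mu), 3 * sdev / sqrt(n))
  expect_lt(abs(sd(draws) - sdev), 3 * sdev / sqrt(2 * (n - 1)))
  for (as_obs in c(4, 6)) {
    p <- hypergeom_pvalue(pairwise_counts_from(ax, ay, as_obs, g0))
    expect_lt(abs(mean(draws >= as_obs) - p), 3 * sqrt(p * (1 - p) / n))
  }
})

test_that("C_hyper is monotone in overlap and in universe size", {
  base <- vapply(0:5, function(s)
    c_hyper(pairwise_counts_from(50, 121, s, 9891)), numeric(1))
  expect_true(all(diff(base) > 0))
  # enlarging the universe strengthens an above-expectation signal
  expect_gt(c_hyper(pairwise_counts_from(50, 121, 5, 23000)),
            c_hyper(pairwise_counts_from(50, 121, 5, 9891)))
})

test_that("the hypergeometric target estimator inverts expected overlap", {
  est <- ga_hat_hyper(pairwise_counts_from(50, 121, 5, 9891))
  expect_equal(est$ga_s_hat, 1210)
  expect_equal(est$pa_hat, 50 * 121 / (5 * 9891), tolerance = 1e-12)
  perfect <- ga_hat_hyper(pairwise_counts_from(7, 7, 7, 100))
  expect_equal(perfect$ga_s_hat, 7)
  expect_error(ga_hat_hyper(pairwise_counts_from(10, 10, 0, 100)),
               "undefined")
})

test_that("mean pairwise C_hyper reproduces the yeast results and skips degenerate pairs", {
  expect_equal(mean_pairwise_c_hyper(yeast_nystatin_matrix(6604))$c_score,
               32.5, tolerance = 0.002)
  expect_equal(mean_pairwise_c_hyper(yeast_nystatin_matrix(4))$c_score,
               0.3464, tolerance = 1e-3)

  # a matrix whose single informative pair sits exactly at expectation
  v <- matrix(0, 16, 2); v[1:4, 1] <- 1; v[c(1, 5:7), 2] <- 1
  m0 <- gene_lineage_matrix(v, g0 = 16)
  expect_equal(mean_pairwise_c_hyper(m0)$c_score, 0)

  # an empty lineage makes its pairs undefined; they are excluded, not zeroed
  v3 <- cbind(v, 0)
  m3 <- gene_lineage_matrix(v3, g0 = 16)
  expect_warning(res <- mean_pairwise_c_hyper(m3), "excluded")
  expect_equal(res$c_score, 0)
})
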