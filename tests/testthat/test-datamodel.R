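test_that("matrix construction enforces the type invariants", {
  v <- matrix(c(1, 0, 0, 1), 2, 2)
  m <- gene_lineage_matrix(v, gene_ids = c("a", "b"),
                           lineage_ids = c("x", "y"), g0 = 10)
  expect_s3_class(m, "gene_lineage_matrix")
  expect_identical(dim(m), c(2L, 2L))
  expect_identical(m$g0, 10L)

  expect_error(gene_lineage_matrix(v, gene_ids = c("a", "a"),
                                   lineage_ids = c("x", "y")),
               "duplicate gene ids")
  expect_error(gene_lineage_matrix(v, g0 = 1), "smaller than")
  expect_error(gene_lineage_matrix(matrix(c(1, -0.1), 1, 2)), "negative score")
  expect_error(gene_lineage_matrix(matrix(c(1, 0.5), 1, 2), mode = "binary"),
               "binary")
  expect_silent(gene_lineage_matrix(matrix(c(1, 0.5), 1, 2),
                                    mode = "continuous"))
})

test_that("read_matrix parses the bundled yeast fixture and rejects bad input", {
  y <- yeast_nystatin_matrix(6604)
  expect_identical(dim(y), c(4L, 20L))
  expect_identical(y$g0, 6604L)
  expect_identical(unname(colSums(y$values)), rep(1, 20))
  expect_identical(unname(rowSums(y$values)), c(11, 7, 1, 1))

  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tl1\tl2", "a\t1\t0", "a\t0\t1"), tmp)
  expect_error(read_matrix(tmp, mode = "binary"), "duplicate gene ids")
  writeLines(c("gene\tl1\tl2", "a\t1\toops"), tmp)
  expect_error(read_matrix(tmp, mode = "binary"), "malformed numeric cell")
  writeLines(c("gene\tl1\tl2", "a\t0.5\t-0.1"), tmp)
  expect_error(read_matrix(tmp, mode = "continuous"), "negative score")
})

test_that("write_matrix / read_matrix round-trips values, ids and g0", {
  m <- random_binary_matrix(g0 = 40, k = 3, a = 6, seed = 11)
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_matrix(m, tmp)
  back <- read_matrix(tmp, mode = "binary", g0 = m$g0)
  expect_equal(back$values, m$values)
  expect_identical(back$gene_ids, m$gene_ids)
  expect_identical(back$lineage_ids, m$lineage_ids)
  expect_identical(back$g0, m$g0)
})

test_that("pairwise_counts counts overlaps and respects symmetry", {
  m <- random_binary_matrix(g0 = 50, k = 3, a = 8, seed = 3)
  cxy <- pairwise_counts(m, 1, 2)
  cyx <- pairwise_counts(m, 2, 1)
  expect_identical(cxy$a_s, cyx$a_s)
  expect_identical(cxy$g0, cyx$g0)
  expect_identical(cxy$a_x, cyx$a_y)
  expect_identical(cxy$a_y, cyx$a_x)

  ident <- gene_lineage_matrix(matrix(c(1, 1, 0, 1, 1, 0), 3, 2), g0 = 5)
  expect_equal(unclass(pairwise_counts(ident, 1, 2))[c("a_x", "a_y", "a_s")],
               list(a_x = 2, a_y = 2, a_s = 2))
  zeros <- gene_lineage_matrix(matrix(0, 3, 2), g0 = 5)
  expect_equal(pairwise_counts(zeros, 1, 2)$a_s, 0)
  expect_error(pairwise_counts(m, 1, "nope"), "unknown lineage")
  expect_warning(pairwise_counts(m, 1, 2, threshold = 0.5), "ignored")

  cont <- gene_lineage_matrix(matrix(c(0.3, 0.05, 0.2, 0.15), 2, 2),
                              mode = "continuous", g0 = 4)
  expect_error(pairwise_counts(cont, 1, 2), "threshold")
  cc <- pairwise_counts(cont, 1, 2, threshold = 0.1)
  expect_equal(c(cc$a_x, cc$a_y, cc$a_s), c(1, 2, 1))
})

test_that("pairwise count validation rejects impossible configurations", {
  expect_error(pairwise_counts_from(5, 5, 6, 10), "exceed min")
  expect_error(pairwise_counts_from(11, 5, 5, 10), "exceed g0")
  expect_error(pairwise_counts_from(8, 8, 2, 10), "feasible minimum")
})

test_that("occupancy histograms cover the implicit zero genes", {
  y <- yeast_nystatin_matrix(6604)
  occ <- occupancy(y)
  expect_identical(occ$k, 20L)
  expect_equal(sum(occ$counts), 6604)
  expect_equal(unname(occ$counts[c("11", "7", "1")]), c(1, 1, 2))

  co <- conifer_occupancy()
  expect_equal(unname(co$counts[c("2", "1", "0")]), c(5, 161, 9725))

  empty <- gene_lineage_matrix(matrix(0, 0, 2), gene_ids = character(0),
                               lineage_ids = c("x", "y"), g0 = 10)
  expect_equal(unname(occupancy(empty)$counts), c(10, 0, 0))
})

test_that("occupancy mass equals total evidence for binary matrices", {
  for (seed in 1:5) {
    m <- random_binary_matrix(g0 = 60, k = 4, a = 7, seed = seed)
    occ <- occupancy(m)
    o <- as.integer(names(occ$counts))
    expect_equal(sum(o * occ$counts), sum(m$values))
  }
})

test_that("the conifer fixture carries the published counts", {
  cc <- conifer_counts("mcmt")
  expect_equal(c(cc$a_x, cc$a_y, cc$a_s, cc$g0), c(50, 121, 5, 9891))
  ahm <- conifer_counts("ahm_spruce_vs_pine_mcmt")
  expect_equal(c(ahm$a_x, ahm$a_y, ahm$a_s), c(50, 23, 1))
})
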