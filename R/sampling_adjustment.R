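#' Sampling-adjusted hypergeometric effect size
#'
#' When the assayed genes are a random fraction q of the mutational target,
#' C_hyper computed on the sampled counts is biased (multiplying all inputs
#' of the formula by a common factor changes its value). If q can be
#' estimated, the bias is removed by dividing every input — a_x, a_y, a_s and
#' g0 — by q before evaluating [c_hyper()]; the adjusted counts are
#' real-valued and are not rounded. No p-value accompanies the adjusted
#' score: the exact tail probability is undefined for fractional counts.
#'
#' @param counts a `pairwise_counts` object from the sampled data.
#' @param q fraction of the gene universe sampled, in (0, 1].
#' @return the adjusted C_hyper, a single number (or `NA` with a warning when
#'   the null SD is zero).
#' @export
c_hyper_adj <- function(counts, q) {
  stopifnot(inherits(counts, "pairwise_counts"))
  if (!is.numeric(q) || length(q) != 1L || !is.finite(q) || q <= 0 || q > 1)
    stop("q must lie in (0, 1]")
  c_hyper(pairwise_counts_from(counts$a_x / q, counts$a_y / q,
                               counts$a_s / q, counts$g0 / q))
}

#' Sampling-adjusted permutation chi-square effect size
#'
#' Resampling extension of [c_chisq()] for incompletely sampled gene
#' universes. Each of `n_resamples` replicates restores the dataset to its
#' estimated full size G = round(g0 / q) by appending round(G * (1 - q))
#' whole gene rows drawn with replacement from the existing universe (a
#' gene's scores across lineages stay together, preserving the cross-lineage
#' structure that carries the repeatability signal; implicit all-zero genes
#' can be drawn too), then computes [c_chisq()] on the extended matrix. The
#' replicate mean is the adjusted score and the replicate SD its resampling
#' uncertainty.
#'
#' @param x a [gene_lineage_matrix()] of the sampled genes.
#' @param q fraction of the gene universe sampled, in (0, 1].
#' @param n_resamples number of resampling replicates.
#' @param n_permutations permutations per replicate for the chi-square null.
#' @param seed master seed; per-replicate seeds are derived from it.
#' @return a `constraint_result` whose `c_score` is the replicate mean; the
#'   replicate SD and the per-replicate scores are attached as attributes
#'   `resample_sd` and `resample_scores`.
#' @export
c_chisq_adj <- function(x, q, n_resamples = 50, n_permutations = 10000,
                        seed = 1L) {
  stopifnot(inherits(x, "gene_lineage_matrix"))
  if (!is.numeric(q) || length(q) != 1L || !is.finite(q) || q <= 0 || q > 1)
    stop("q must lie in (0, 1]")
  if (!is_count(n_resamples) || n_resamples < 1)
    stop("n_resamples must be a positive integer")
  G <- round(x$g0 / q)
  n_add <- round(G * (1 - q))
  if (n_add == 0) {
    res <- c_chisq(x, n_permutations, seed)
    attr(res, "resample_sd") <- 0
    attr(res, "resample_scores") <- res$c_score
    attr(res, "n_resamples") <- 1L
    return(res)
  }
  n_obs <- nrow(x$values)
  scores <- with_seed(seed, {
    draws <- matrix(sample.int(x$g0, n_add * n_resamples, replace = TRUE),
                    nrow = n_add)
    vapply(seq_len(n_resamples), function(r) {
      idx <- draws[, r]
      explicit <- idx[idx <= n_obs]           # rows beyond n_obs are all-zero
      extra <- x$values[explicit, , drop = FALSE]
      ext <- gene_lineage_matrix(
        rbind(x$values, extra),
        gene_ids = c(x$gene_ids, sprintf("resample_%d_%d", r,
                                         seq_len(nrow(extra)))),
        lineage_ids = x$lineage_ids,
        g0 = x$g0 + n_add, mode = x$mode)
      c_chisq(ext, n_permutations, derive_seed(seed, r))$c_score
    }, numeric(1))
  })
  res <- constraint_result(mean(scores), null_mean = NA_real_,
                           null_sd = NA_real_,
                           n_permutations = n_permutations, seed = seed,
                           method = if (x$mode == "binary") "chisq_binary"
                                    else "chisq_continuous")
  attr(res, "resample_sd") <- stats::sd(scores)
  attr(res, "resample_scores") <- scores
  attr(res, "n_resamples") <- as.integer(n_resamples)
  res
}
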