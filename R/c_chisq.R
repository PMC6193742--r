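#' Rescale continuous scores to [0, 1]
#'
#' Affine rescaling of continuous evidence scores, (x - min) / (max - min).
#' Within-lineage scaling (the default used throughout) removes differences
#' among lineages in the absolute magnitude of the evidence index, which is
#' desirable when scores span many orders of magnitude (a GWAS p of 1e-10 and
#' one of 1e-20 are both strong evidence). When some lineages genuinely carry
#' stronger signal at more loci, global scaling preserves those differences.
#' Minima and maxima are taken over the explicit rows of the matrix.
#'
#' @param x a continuous [gene_lineage_matrix()].
#' @param scope `"within_lineage"` (each column rescaled by its own range) or
#'   `"global"` (one range for the whole matrix).
#' @return a continuous `gene_lineage_matrix` with values in [0, 1].
#' @export
standardize_scores <- function(x, scope = c("within_lineage", "global")) {
  stopifnot(inherits(x, "gene_lineage_matrix"))
  scope <- match.arg(scope)
  if (x$mode != "continuous")
    stop("standardization applies to continuous matrices")
  v <- x$values
  if (scope == "within_lineage") {
    rng <- apply(v, 2, range)
    flat <- which(rng[2, ] - rng[1, ] <= 0)
    if (length(flat))
      stop("constant scores in lineage(s): ",
           paste(x$lineage_ids[flat], collapse = ", "))
    v <- sweep(sweep(v, 2, rng[1, ], "-"), 2, rng[2, ] - rng[1, ], "/")
  } else {
    r <- range(v)
    if (diff(r) <= 0) stop("all scores are constant; cannot standardize")
    v <- (v - r[1]) / diff(r)
  }
  gene_lineage_matrix(v, x$gene_ids, x$lineage_ids, g0 = x$g0,
                      mode = "continuous")
}

#' Goodness-of-fit statistic for multi-lineage repeatability
#'
#' Sums each gene's evidence across lineages (o_i for binary data, the score
#' total for continuous data) and measures its dispersion over all g0 genes
#' in the universe against the equal-use expectation e = (total evidence)/g0:
#' chi^2 = sum_i (o_i - e)^2 / e. Implicit all-zero genes are included. For
#' binary data this is Pearson's chi-square statistic; for continuous data it
#' is the analogous dispersion of score sums.
#'
#' @param x a [gene_lineage_matrix()] with positive total evidence.
#' @return the statistic, a single non-negative number.
#' @export
chisq_stat <- function(x) {
  stopifnot(inherits(x, "gene_lineage_matrix"))
  chisq_from_rowsums(rowSums(x$values), x$g0)
}

# chi^2 over the full universe from the explicit row sums; zero rows enter
# through the identity sum((r - e)^2)/e = sum(r^2)/e - S with S = g0 * e.
chisq_from_rowsums <- function(r, g0) {
  S <- sum(r)
  if (S <= 0) stop("total evidence is zero; chi-square statistic undefined")
  e <- S / g0
  sum(r^2) / e - S
}

#' Permutation null distribution of the chi-square statistic
#'
#' Simulates the statistic's distribution under the null hypothesis that
#' every gene in the g0-gene universe is equally likely to carry each
#' lineage's evidence: each replicate independently permutes every lineage's
#' scores across the full universe (equivalently, reassigns its nonzero
#' scores to positions drawn without replacement among g0) and recomputes
#' [chisq_stat()].
#'
#' @param x a [gene_lineage_matrix()].
#' @param n_permutations number of null replicates.
#' @param seed integer seed; the caller's RNG state is left untouched.
#' @return a `permutation_null` object: `stats` (numeric vector of simulated
#'   statistics), `n_permutations`, `seed`, `scope`.
#' @export
permutation_null <- function(x, n_permutations = 10000, seed = 1L) {
  stopifnot(inherits(x, "gene_lineage_matrix"))
  if (!is_count(n_permutations) || n_permutations < 1)
    stop("n_permutations must be a positive integer")
  S <- sum(x$values)
  if (S <= 0) stop("total evidence is zero; chi-square statistic undefined")
  g0 <- x$g0
  e <- S / g0
  # sparse representation: per lineage, the nonzero scores to scatter
  per_lin <- lapply(seq_len(ncol(x$values)), function(j) {
    v <- x$values[, j]
    v[v > 0]
  })
  per_lin <- per_lin[lengths(per_lin) > 0]
  vals <- unlist(per_lin, use.names = FALSE)
  ns <- lengths(per_lin)
  stats <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(b) {
      pos <- unlist(lapply(ns, function(n) sample.int(g0, n)),
                    use.names = FALSE)
      sums <- rowsum(vals, pos, reorder = FALSE)
      sum(sums^2) / e - S
    }, numeric(1))
  })
  structure(list(stats = stats, n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed), scope = "all_lineages"),
            class = "permutation_null")
}

#' Simultaneous multi-lineage permutation test
#'
#' Tests, across all lineages at once, whether evidence of adaptation is more
#' concentrated on particular genes than expected if all g0 genes were
#' equally available. The p-value is the proportion of permutation-null
#' statistics at least as large as the observed [chisq_stat()] (inclusive
#' comparison, conservative under the heavy ties of discrete data; set
#' `strict_greater = TRUE` for the strict "exceeds" proportion). A p of 0
#' should be read as "< 1/n_permutations".
#'
#' @inheritParams permutation_null
#' @param strict_greater use strictly-greater instead of >= when counting
#'   null exceedances.
#' @param add_one use the (b + 1)/(B + 1) estimator instead of the plain
#'   proportion.
#' @return a `constraint_result` whose `c_score` is the observed statistic
#'   and whose `p_value`, `null_mean`, `null_sd` summarize the test.
#' @export
permutation_pvalue <- function(x, n_permutations = 10000, seed = 1L,
                               strict_greater = FALSE, add_one = FALSE) {
  obs <- chisq_stat(x)
  null <- permutation_null(x, n_permutations, seed)
  b <- if (strict_greater) sum(null$stats > obs) else sum(null$stats >= obs)
  p <- if (add_one) (b + 1) / (n_permutations + 1) else b / n_permutations
  constraint_result(obs, p_value = p, null_mean = mean(null$stats),
                    null_sd = stats::sd(null$stats),
                    n_permutations = n_permutations, seed = seed,
                    method = if (x$mode == "binary") "chisq_binary"
                             else "chisq_continuous")
}

#' Permutation chi-square repeatability effect size C_chisq
#'
#' Effect size analogous to [c_hyper()] for binary or continuous evidence:
#' for each unordered pair of lineages, the observed two-lineage chi-square
#' statistic is standardized by the mean and SD of its own permutation null,
#' C = (chi2 - mean(chi2_sim)) / sd(chi2_sim), and the pairwise C values are
#' averaged. Averaging over pairs keeps the effect size independent of the
#' number of lineages sampled, while the attached p-value comes from the
#' simultaneous all-lineage test, which gains power from every lineage.
#' Per-pair null seeds are derived deterministically from `seed`.
#'
#' @inheritParams permutation_pvalue
#' @return a `constraint_result`: `c_score` is the mean pairwise C_chisq;
#'   `p_value`, `null_mean`, `null_sd` are from the simultaneous test.
#' @export
c_chisq <- function(x, n_permutations = 10000, seed = 1L,
                    strict_greater = FALSE, add_one = FALSE) {
  stopifnot(inherits(x, "gene_lineage_matrix"))
  k <- ncol(x$values)
  if (k < 2) stop("need at least two lineages")
  if (n_permutations < 100)
    stop("n_permutations must be at least 100 for a usable null SD")
  pairs <- utils::combn(k, 2)
  cs <- numeric(ncol(pairs))
  for (p in seq_len(ncol(pairs))) {
    sub <- gene_lineage_matrix(x$values[, pairs[, p], drop = FALSE],
                               x$gene_ids, x$lineage_ids[pairs[, p]],
                               g0 = x$g0, mode = x$mode)
    obs <- chisq_stat(sub)
    null <- permutation_null(sub, n_permutations, derive_seed(seed, p))
    sdn <- stats::sd(null$stats)
    if (!is.finite(sdn) || sdn <= 0) {
      warning("zero null SD for lineage pair (", x$lineage_ids[pairs[1, p]],
              ", ", x$lineage_ids[pairs[2, p]], "); pair skipped")
      cs[p] <- NA_real_
    } else {
      cs[p] <- (obs - mean(null$stats)) / sdn
    }
  }
  if (all(is.na(cs))) stop("C_chisq undefined for every lineage pair")
  simultaneous <- permutation_pvalue(x, n_permutations, derive_seed(seed, 0L),
                                     strict_greater = strict_greater,
                                     add_one = add_one)
  constraint_result(mean(cs, na.rm = TRUE), p_value = simultaneous$p_value,
                    null_mean = simultaneous$null_mean,
                    null_sd = simultaneous$null_sd,
                    n_permutations = n_permutations, seed = seed,
                    method = simultaneous$method)
}
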