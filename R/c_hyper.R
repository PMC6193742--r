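#' Expected overlap between two lineages under the no-constraint null
#'
#' If a_x and a_y genes are adapted in two lineages and every one of the g0
#' genes in the universe is equally likely to be used, the number of shared
#' adapted genes a_s follows a hypergeometric distribution with mean
#' a_x * a_y / g0.
#'
#' @param counts a `pairwise_counts` object (see [pairwise_counts()]).
#' @return the expected overlap, a single number.
#' @export
expected_overlap <- function(counts) {
  stopifnot(inherits(counts, "pairwise_counts"))
  counts$a_x * counts$a_y / counts$g0
}

#' Hypergeometric repeatability effect size C_hyper
#'
#' Standardizes the observed overlap by the mean and standard deviation of
#' the hypergeometric null:
#' \deqn{C = \frac{a_s - a_x a_y / g_0}
#'   {\sqrt{a_x a_y (g_0 - a_x)(g_0 - a_y) / (g_0^2 (g_0 - 1))}}}
#' C is the number of null standard deviations by which the observed gene
#' reuse exceeds chance expectation; it is comparable across traits and
#' species. The formula is algebraic, so real-valued (e.g. sampling-adjusted)
#' counts are accepted. When the null has zero variance (a lineage with no
#' adapted genes, or one that adapts every gene) the score is undefined and
#' `NA` is returned with a warning.
#'
#' @param counts a `pairwise_counts` object.
#' @return a single number, or `NA` when the null standard deviation is zero.
#' @seealso [hypergeom_pvalue()], [mean_pairwise_c_hyper()], [c_hyper_adj()]
#' @export
c_hyper <- function(counts) {
  stopifnot(inherits(counts, "pairwise_counts"))
  a_x <- as.double(counts$a_x); a_y <- as.double(counts$a_y)
  a_s <- as.double(counts$a_s); g0 <- as.double(counts$g0)
  var0 <- a_x * a_y * (g0 - a_x) * (g0 - a_y) / (g0^2 * (g0 - 1))
  if (!is.finite(var0) || var0 <= 0) {
    warning("C_hyper undefined: null standard deviation is zero ",
            "(a lineage with 0 or g0 adapted genes, or g0 <= 1)")
    return(NA_real_)
  }
  (a_s - a_x * a_y / g0) / sqrt(var0)
}

#' Exact hypergeometric overlap p-value
#'
#' Upper-tail probability of observing `a_s` or more shared adapted genes
#' when `a_x` draws are made without replacement from a universe of `g0`
#' genes of which `a_y` are "successes" (the roles of x and y are
#' interchangeable). Counts must be integers: the tail probability is not
#' defined for fractional (sampling-adjusted) counts.
#'
#' @param counts a `pairwise_counts` object with integer counts.
#' @return P(X >= a_s), a probability in [0, 1].
#' @export
hypergeom_pvalue <- function(counts) {
  stopifnot(inherits(counts, "pairwise_counts"))
  with(counts, {
    for (v in c(a_x, a_y, a_s, g0))
      if (v != floor(v))
        stop("hypergeometric p-value requires integer counts")
    stats::phyper(a_s - 1, a_y, g0 - a_y, a_x, lower.tail = FALSE)
  })
}

#' Hypergeometric estimator of the effective adaptive target
#'
#' Inverts the expected-overlap relation to estimate the number of genes
#' effectively available to adaptation: ga_s = a_x * a_y / a_s, and the
#' proportion of the genome available, Pa = a_x * a_y / (a_s * n_s). Undefined
#' when no overlap is observed (a_s = 0).
#'
#' @param counts a `pairwise_counts` object with `a_s > 0`.
#' @param n_s number of shared genes in the genome used to express the
#'   estimate as a proportion; defaults to the `g0` of `counts`.
#' @return an `adaptive_target_estimate` with `method = "hypergeometric"`.
#' @export
ga_hat_hyper <- function(counts, n_s = counts$g0) {
  stopifnot(inherits(counts, "pairwise_counts"))
  if (counts$a_s <= 0)
    stop("ga_s is undefined when the observed overlap a_s is zero")
  ga <- counts$a_x * counts$a_y / counts$a_s
  adaptive_target_estimate(ga_s_hat = ga, pa_hat = ga / n_s,
                           loglik = NA_real_, method = "hypergeometric",
                           search_bounds = c(NA_integer_, NA_integer_))
}

#' Mean pairwise C_hyper across lineages
#'
#' The multi-lineage effect size is the arithmetic mean of [c_hyper()] over
#' all k(k-1)/2 unordered lineage pairs, so it measures the per-bout excess
#' repeatability and does not grow with the number of lineages sampled. Pairs
#' with an undefined score (zero null SD) are excluded with a warning.
#'
#' @param x a binary [gene_lineage_matrix()] with at least two lineages, or a
#'   continuous one with `threshold`.
#' @param threshold binarization cutoff for continuous matrices.
#' @return a `constraint_result` with `method = "hyper"`; its `c_score` is the
#'   mean pairwise C_hyper (no p-value: use [hypergeom_pvalue()] pairwise or
#'   [permutation_pvalue()] for a simultaneous test).
#' @export
mean_pairwise_c_hyper <- function(x, threshold = NULL) {
  stopifnot(inherits(x, "gene_lineage_matrix"))
  k <- ncol(x$values)
  if (k < 2) stop("need at least two lineages")
  pairs <- utils::combn(k, 2)
  scores <- numeric(ncol(pairs))
  for (p in seq_len(ncol(pairs))) {
    cc <- pairwise_counts(x, pairs[1, p], pairs[2, p], threshold = threshold)
    scores[p] <- withCallingHandlers(c_hyper(cc),
      warning = function(w) invokeRestart("muffleWarning"))
  }
  n_undef <- sum(is.na(scores))
  if (n_undef == ncol(pairs)) {
    warning("C_hyper undefined for every lineage pair")
    return(constraint_result(NA_real_, method = "hyper"))
  }
  if (n_undef > 0)
    warning(n_undef, " of ", ncol(pairs),
            " lineage pairs had undefined C_hyper and were excluded")
  constraint_result(mean(scores, na.rm = TRUE), method = "hyper")
}

#' Container for a repeatability effect size
#'
#' @param c_score the effect size (C-score).
#' @param p_value attached p-value, or `NA`.
#' @param null_mean,null_sd moments of the null distribution used for
#'   standardization, when simulated.
#' @param n_permutations,seed provenance of a simulated null.
#' @param method one of `"hyper"`, `"chisq_binary"`, `"chisq_continuous"`.
#' @return a `constraint_result` object.
#' @export
constraint_result <- function(c_score, p_value = NA_real_,
                              null_mean = NA_real_, null_sd = NA_real_,
                              n_permutations = 0L, seed = NA_integer_,
                              method = c("hyper", "chisq_binary",
                                         "chisq_continuous")) {
  method <- match.arg(method)
  if (!is.na(p_value) && (p_value < 0 || p_value > 1))
    stop("p_value must lie in [0, 1]")
  if (!is.na(null_sd) && null_sd < 0) stop("null_sd must be >= 0")
  structure(list(c_score = c_score, p_value = p_value, null_mean = null_mean,
                 null_sd = null_sd, n_permutations = as.integer(n_permutations),
                 seed = seed, method = method),
            class = "constraint_result")
}

#' @export
print.constraint_result <- function(x, ...) {
  cat(sprintf("constraint_result (%s): C = %s\n", x$method,
              format(x$c_score, digits = 4)))
  if (!is.na(x$p_value)) {
    p <- if (x$p_value == 0 && x$n_permutations > 0)
      sprintf("< %g", 1 / x$n_permutations) else format(x$p_value, digits = 3)
    cat(sprintf("  p = %s (%d permutations, seed %s)\n", p,
                x$n_permutations, format(x$seed)))
  }
  if (!is.na(x$null_mean))
    cat(sprintf("  null mean = %.4g, null sd = %.4g\n", x$null_mean, x$null_sd))
  invisible(x)
}

#' Container for an adaptive-target estimate
#'
#' @param ga_s_hat estimated effective number of genes available to adaptation.
#' @param pa_hat `ga_s_hat` as a proportion of the genome.
#' @param loglik log-likelihood at the optimum (`NA` for the closed-form
#'   hypergeometric estimator).
#' @param method `"hypergeometric"` or `"likelihood"`.
#' @param search_bounds integer search interval used by the optimizer.
#' @return an `adaptive_target_estimate` object.
#' @export
adaptive_target_estimate <- function(ga_s_hat, pa_hat, loglik,
                                     method = c("hypergeometric", "likelihood"),
                                     search_bounds = c(NA_integer_, NA_integer_)) {
  method <- match.arg(method)
  if (ga_s_hat <= 0) stop("ga_s_hat must be positive")
  if (pa_hat <= 0 || pa_hat > 1 + 1e-9)
    stop("pa_hat must lie in (0, 1]")
  structure(list(ga_s_hat = ga_s_hat, pa_hat = pa_hat, loglik = loglik,
                 method = method, search_bounds = search_bounds),
            class = "adaptive_target_estimate")
}

#' @export
print.adaptive_target_estimate <- function(x, ...) {
  cat(sprintf("adaptive_target_estimate (%s): ga_s = %s, Pa = %.4g\n",
              x$method, format(x$ga_s_hat, digits = 6), x$pa_hat))
  if (!is.na(x$loglik))
    cat(sprintf("  log-likelihood at optimum = %.4f (search %d..%d)\n",
                x$loglik, x$search_bounds[1], x$search_bounds[2]))
  invisible(x)
}
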