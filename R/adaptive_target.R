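#' Occupancy probability under the binomial-mixture model
#'
#' Probability of observing a gene adapted in `o_i` of `k` lineages when a
#' proportion `pa` of the genome belongs to the effective adaptive target
#' (within which each gene contributes independently in each lineage with
#' probability `obar`) and the remaining genes can never contribute:
#' \deqn{\zeta_i = P_a \, \mathrm{Bin}(k, \bar o, o_i)
#'   + (1 - P_a)\, \mathrm{Bin}(k, 0, o_i)}
#' where Bin(n, y, x) is the binomial probability of x successes in n trials
#' of probability y; Bin(k, 0, o_i) is the point mass at zero.
#'
#' @param o_i observed occupancy, an integer in 0..k.
#' @param k number of lineages.
#' @param obar per-lineage contribution probability of a target gene, in
#'   [0, 1].
#' @param pa proportion of the genome in the target, in [0, 1].
#' @return a probability in [0, 1].
#' @export
zeta <- function(o_i, k, obar, pa) {
  if (!is_count(o_i) || !is_count(k) || o_i > k)
    stop("o_i must be an integer in 0..k")
  if (obar < 0 || obar > 1) stop("obar must lie in [0, 1]")
  if (pa < 0 || pa > 1) stop("pa must lie in [0, 1]")
  pa * stats::dbinom(o_i, k, obar) + (1 - pa) * as.numeric(o_i == 0)
}

#' Profile log-likelihood of the effective adaptive target size
#'
#' For a candidate target size ga_s, the occupancy model fixes both mixture
#' parameters: pa = ga_s / g0 and obar = sum(o_i) / (ga_s * k) (the total
#' evidence spread over the target). The log-likelihood is the sum of
#' log [zeta()] over all g0 genes, computed from the occupancy histogram.
#' Returns -Inf when a positive-count occupancy class has zero probability
#' (e.g. at the boundary obar = 1 with intermediate occupancies observed).
#'
#' @param ga_s candidate target size, in [sum(o)/k, g0].
#' @param occ an `occupancy_counts` object (see [occupancy()]).
#' @return the log-likelihood, possibly `-Inf`.
#' @export
log_likelihood <- function(ga_s, occ) {
  stopifnot(inherits(occ, "occupancy_counts"))
  S <- sum(as.integer(names(occ$counts)) * occ$counts)
  if (ga_s * occ$k < S - 1e-9)
    stop("ga_s = ", ga_s, " below the lower bound sum(o)/k = ", S / occ$k)
  if (ga_s > occ$g0) stop("ga_s cannot exceed g0 = ", occ$g0)
  obar <- min(1, S / (ga_s * occ$k))
  pa <- ga_s / occ$g0
  os <- as.integer(names(occ$counts))
  z <- pa * stats::dbinom(os, occ$k, obar) + (1 - pa) * as.numeric(os == 0)
  nonzero <- occ$counts > 0
  if (any(z[nonzero] <= 0)) return(-Inf)
  sum(occ$counts[nonzero] * log(z[nonzero]))
}

#' Maximum-likelihood estimate of the effective adaptive target
#'
#' Maximizes [log_likelihood()] over integer ga_s between
#' max(ceiling(sum(o)/k), number of genes ever observed adapted) and g0.
#' Every observed adapted gene must belong to the target, hence the second
#' term of the lower bound. The search is an exhaustive integer grid when the
#' interval holds at most `grid_limit` values, otherwise golden-section
#' search on the continuous relaxation followed by an integer neighborhood
#' check.
#'
#' @param occ an `occupancy_counts` object with at least one gene of positive
#'   occupancy.
#' @param n_s genome size used to express the estimate as a proportion
#'   (Pa = ga_s / n_s); defaults to the occupancy's g0, but a whole-genome
#'   size can be supplied to extrapolate beyond the sampled universe.
#' @param grid_limit largest search interval for which the exhaustive grid is
#'   used.
#' @return an `adaptive_target_estimate` with `method = "likelihood"`.
#' @export
mle_ga <- function(occ, n_s = occ$g0, grid_limit = 1e5) {
  stopifnot(inherits(occ, "occupancy_counts"))
  os <- as.integer(names(occ$counts))
  S <- sum(os * occ$counts)
  n_pos <- sum(occ$counts[os > 0])
  if (S == 0) stop("all occupancies are zero; nothing to estimate")
  lo <- max(ceiling(S / occ$k), n_pos)
  hi <- occ$g0
  if (lo > hi) stop("lower search bound exceeds g0")
  ll <- function(g) log_likelihood(g, occ)
  if (hi - lo + 1 <= grid_limit) {
    grid <- lo:hi
    vals <- vapply(grid, ll, numeric(1))
    best <- grid[which.max(vals)]
  } else {
    opt <- stats::optimize(ll, lower = lo, upper = hi, maximum = TRUE,
                           tol = 0.5)
    cand <- unique(pmin(hi, pmax(lo,
      c(floor(opt$maximum), ceiling(opt$maximum), lo, hi))))
    cand <- sort(unique(c(cand, cand - 1L, cand + 1L)))
    cand <- cand[cand >= lo & cand <= hi]
    best <- cand[which.max(vapply(cand, ll, numeric(1)))]
  }
  adaptive_target_estimate(ga_s_hat = as.integer(best),
                           pa_hat = best / n_s,
                           loglik = ll(best), method = "likelihood",
                           search_bounds = c(as.integer(lo), as.integer(hi)))
}
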