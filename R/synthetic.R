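#' Sorted-pair generator of tunable repeatability
#'
#' Generates a two-lineage binary dataset with a controllable excess of gene
#' reuse: `a_small` adapted genes are placed uniformly in lineage 1 and
#' `a_small + a_offset` in lineage 2 (the offset, 20 by default, keeps the
#' two lineages from being trivially identical), then the first
#' round(sort_proportion * g_s) rows of each lineage are sorted in
#' descending order. Sorting pushes each lineage's ones to the top of the
#' sorted block, forcing them to co-occur; `sort_proportion = 0` gives pure
#' chance overlap and `sort_proportion = 1` forces maximal overlap. Column
#' sums are always (a_small, a_small + a_offset).
#'
#' @param g_s number of genes per lineage (also used as g0).
#' @param a_small adapted genes in lineage 1.
#' @param a_offset extra adapted genes in lineage 2.
#' @param sort_proportion fraction of rows sorted, in [0, 1].
#' @param seed integer seed.
#' @return a binary [gene_lineage_matrix()] with `g0 = g_s`.
#' @export
generate_sorted_pair <- function(g_s = 200, a_small = 10, a_offset = 20,
                                 sort_proportion = 0, seed = 1L) {
  if (!is_count(g_s) || !is_count(a_small) || !is_count(a_offset))
    stop("g_s, a_small and a_offset must be non-negative integers")
  if (a_small + a_offset > g_s)
    stop("a_small + a_offset cannot exceed g_s")
  if (sort_proportion < 0 || sort_proportion > 1)
    stop("sort_proportion must lie in [0, 1]")
  with_seed(seed, {
    v <- matrix(0, g_s, 2)
    v[sample.int(g_s, a_small), 1] <- 1
    v[sample.int(g_s, a_small + a_offset), 2] <- 1
    n_sort <- round(sort_proportion * g_s)
    if (n_sort > 1) {
      top <- seq_len(n_sort)
      v[top, 1] <- sort(v[top, 1], decreasing = TRUE)
      v[top, 2] <- sort(v[top, 2], decreasing = TRUE)
    }
    gene_lineage_matrix(v, gene_ids = paste0("g", seq_len(g_s)),
                        lineage_ids = c("lineage1", "lineage2"),
                        g0 = g_s, mode = "binary")
  })
}

#' Configuration for the two-patch simulator
#'
#' @param n_large,n_small numbers of loci with allelic effects
#'   `effect_large` / `effect_small`.
#' @param effect_large,effect_small absolute allelic effect sizes.
#' @param N_per_patch diploid individuals per patch.
#' @param migration_rate per-generation probability that an individual is
#'   swapped to the other patch.
#' @param optima phenotypic optima of the two patches.
#' @param fitness_cost_at_opposite fitness of a perfectly adapted resident
#'   placed at the other optimum is `1 - fitness_cost_at_opposite`; this
#'   calibrates the width of the Gaussian fitness function.
#' @param mutation_rate per-allele, per-generation probability of a sign
#'   flip.
#' @param generations generations to run.
#' @param census_interval generations between F_ST censuses.
#' @param seed integer seed.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_large = 10, n_small = 90,
                              effect_large = 0.1, effect_small = 0.01,
                              N_per_patch = 500, migration_rate = 0.005,
                              optima = c(1, -1),
                              fitness_cost_at_opposite = 0.5,
                              mutation_rate = 1e-5,
                              generations = 2000, census_interval = 100,
                              seed = 1L) {
  stopifnot(is_count(n_large), is_count(n_small), n_large + n_small >= 1,
            is_count(N_per_patch), N_per_patch >= 2,
            migration_rate >= 0, migration_rate <= 1,
            length(optima) == 2,
            fitness_cost_at_opposite >= 0, fitness_cost_at_opposite < 1,
            mutation_rate >= 0, mutation_rate <= 1,
            is_count(generations), is_count(census_interval),
            generations >= census_interval)
  structure(list(n_large = n_large, n_small = n_small,
                 effect_large = effect_large, effect_small = effect_small,
                 N_per_patch = N_per_patch, migration_rate = migration_rate,
                 optima = optima,
                 fitness_cost_at_opposite = fitness_cost_at_opposite,
                 mutation_rate = mutation_rate, generations = generations,
                 census_interval = census_interval, seed = as.integer(seed)),
            class = "simulation_config")
}

#' Two-patch Wright-Fisher simulation under migration-selection balance
#'
#' Individual-based diploid simulation of local adaptation: two patches of N
#' individuals with phenotypic optima `optima[1]` and `optima[2]`, an
#' additive trait controlled by biallelic loci with allelic effects
#' +/- effect (large- and small-effect classes), Gaussian viability selection
#' \eqn{w = \exp(-(z - \theta)^2 / (2\omega^2))} with \eqn{\omega^2}
#' calibrated so that a resident perfectly adapted to one optimum has fitness
#' `1 - fitness_cost_at_opposite` at the other, random mating within patch,
#' free recombination (each parent transmits one allele per locus
#' independently), sign-flip mutation, and symmetric migration. Populations
#' start monomorphic with allele signs drawn at random per locus. Per-locus
#' F_ST between the patches is recorded every `census_interval` generations.
#'
#' This is a deliberately minimal model of the migration-selection-balance
#' setting in which large-effect alleles resist swamping by gene flow while
#' small-effect alleles do not: no genetic map, no stage structure, no
#' selfing.
#'
#' @param cfg a [simulation_config()].
#' @return an `fst_series` object: `fst` (census x locus matrix of F_ST
#'   values), `effect_class` (per-locus `"large"`/`"small"` labels),
#'   `generations` (census times) and the config.
#' @export
simulate_two_patch <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  L <- cfg$n_large + cfg$n_small
  eff <- c(rep(cfg$effect_large, cfg$n_large),
           rep(cfg$effect_small, cfg$n_small))
  N <- cfg$N_per_patch
  # omega^2 from exp(-d^2/(2 omega^2)) = 1 - cost, d = |theta1 - theta2|
  d2 <- diff(cfg$optima)^2
  omega2 <- if (cfg$fitness_cost_at_opposite > 0)
    d2 / (-2 * log(1 - cfg$fitness_cost_at_opposite)) else Inf
  census_at <- seq(cfg$census_interval, cfg$generations,
                   by = cfg$census_interval)
  with_seed(cfg$seed, {
    # X[[p]]: N x L matrix counting '+' alleles per individual (0, 1, 2)
    X <- lapply(1:2, function(p) {
      signs <- sample(c(0L, 2L), L, replace = TRUE)
      matrix(rep(signs, each = N), N, L)
    })
    fst_rec <- matrix(NA_real_, length(census_at), L)
    rec_i <- 1L
    two_sum_eff <- 2 * sum(eff)
    for (gen in seq_len(cfg$generations)) {
      # selection + reproduction within each patch
      for (p in 1:2) {
        z <- 2 * drop(X[[p]] %*% eff) - two_sum_eff
        w <- if (is.finite(omega2))
          exp(-(z - cfg$optima[p])^2 / (2 * omega2)) else rep(1, N)
        if (!all(is.finite(w))) stop("non-finite fitness")
        if (sum(w) <= 0) w <- rep(1, N)
        mothers <- sample.int(N, N, replace = TRUE, prob = w)
        fathers <- sample.int(N, N, replace = TRUE, prob = w)
        gm <- matrix(stats::rbinom(N * L, 1L, X[[p]][mothers, ] / 2), N, L)
        gf <- matrix(stats::rbinom(N * L, 1L, X[[p]][fathers, ] / 2), N, L)
        X[[p]] <- gm + gf
      }
      # mutation: sign flips at random alleles, Poisson-thinned
      if (cfg$mutation_rate > 0) {
        n_mut <- stats::rpois(1, 2 * N * L * 2 * cfg$mutation_rate)
        if (n_mut > 0) {
          patch <- sample.int(2, n_mut, replace = TRUE)
          cell <- sample.int(N * L, n_mut, replace = TRUE)
          for (mte in seq_len(n_mut)) {
            x <- X[[patch[mte]]][cell[mte]]
            # one of the two alleles flips; it is '+' with probability x/2
            X[[patch[mte]]][cell[mte]] <-
              if (stats::runif(1) < x / 2) x - 1L else x + 1L
          }
        }
      }
      # symmetric migration: swap a binomial number of individuals
      if (cfg$migration_rate > 0) {
        n_mig <- stats::rbinom(1, N, cfg$migration_rate)
        if (n_mig > 0) {
          i1 <- sample.int(N, n_mig)
          i2 <- sample.int(N, n_mig)
          tmp <- X[[1]][i1, , drop = FALSE]
          X[[1]][i1, ] <- X[[2]][i2, , drop = FALSE]
          X[[2]][i2, ] <- tmp
        }
      }
      if (rec_i <= length(census_at) && gen == census_at[rec_i]) {
        p1 <- colSums(X[[1]]) / (2 * N)
        p2 <- colSums(X[[2]]) / (2 * N)
        fst_rec[rec_i, ] <- fst(p1, p2)
        rec_i <- rec_i + 1L
      }
    }
    structure(list(fst = fst_rec,
                   effect_class = rep(c("large", "small"),
                                      c(cfg$n_large, cfg$n_small)),
                   generations = census_at, config = cfg),
              class = "fst_series")
  })
}

#' @export
print.fst_series <- function(x, ...) {
  cat(sprintf("fst_series: %d loci (%d large, %d small), %d censuses to generation %d\n",
              ncol(x$fst), sum(x$effect_class == "large"),
              sum(x$effect_class == "small"), nrow(x$fst),
              max(x$generations)))
  invisible(x)
}

#' G_ST-style F_ST from two patch allele frequencies
#'
#' 1 - H_S / H_T where H_S is the mean within-patch heterozygosity
#' 2p(1-p) and H_T the heterozygosity at the pooled frequency. Vectorized
#' over loci; 0 by convention when both patches are monomorphic for the same
#' allele (H_T = 0); clamped to [0, 1].
#'
#' @param p1,p2 allele frequencies in the two patches (vectors).
#' @return F_ST values in [0, 1].
#' @export
fst <- function(p1, p2) {
  stopifnot(length(p1) == length(p2),
            all(p1 >= 0 & p1 <= 1), all(p2 >= 0 & p2 <= 1))
  hs <- (2 * p1 * (1 - p1) + 2 * p2 * (1 - p2)) / 2
  pbar <- (p1 + p2) / 2
  ht <- 2 * pbar * (1 - pbar)
  out <- ifelse(ht > 0, 1 - hs / ht, 0)
  pmin(pmax(out, 0), 1)
}

#' Binary classification of adapted loci from an F_ST trajectory
#'
#' A locus is called adapted when its F_ST exceeds `fst_threshold` in
#' strictly more than `fraction` of the last `window` census points —
#' sustained differentiation, robust to single-census fluctuations.
#'
#' @param series an `fst_series` from [simulate_two_patch()].
#' @param fst_threshold F_ST cutoff.
#' @param fraction required fraction of censuses above the cutoff (strict).
#' @param window number of final census points examined.
#' @return an integer vector of 0/1 per locus.
#' @export
classify_adapted <- function(series, fst_threshold = 0.1, fraction = 0.8,
                             window = 25) {
  stopifnot(inherits(series, "fst_series"))
  n <- nrow(series$fst)
  if (n < window)
    stop("series has ", n, " census points; window of ", window, " required")
  tail_fst <- series$fst[(n - window + 1):n, , drop = FALSE]
  above <- colSums(tail_fst > fst_threshold)
  as.integer(above > fraction * window)
}
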