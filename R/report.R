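#' Full repeatability analysis of a gene-by-lineage matrix
#'
#' Convenience wrapper assembling the package's statistics for one dataset
#' and one null hypothesis (one g0): mean pairwise C_hyper, the simultaneous
#' permutation chi-square test and C_chisq, the exact hypergeometric p-value
#' (two-lineage data only), both adaptive-target estimators, similarity
#' indices, and — when a sampling fraction `q` is supplied — the adjusted
#' C-scores. All stochastic components run under `seed` and echo their
#' parameters so every number in the report can be recomputed by calling the
#' underlying function.
#'
#' @param x a [gene_lineage_matrix()].
#' @param threshold binarization cutoff for continuous matrices (used for the
#'   count-based statistics; the chi-square statistics use the scores).
#' @param n_permutations permutations for the chi-square null.
#' @param seed master seed.
#' @param q optional sampled fraction of the gene universe, in (0, 1].
#' @param n_resamples resampling replicates for the adjusted C_chisq.
#' @param g_s optional independent estimate of the mutational-target size,
#'   used only by the interpretation text.
#' @param alpha significance level used to operationalize "consistent with
#'   the null" in the interpretation.
#' @return a `constraint_report` list; `print()` gives a human-readable
#'   summary and [write_report()] a machine-readable JSON one.
#' @export
run_analysis <- function(x, threshold = NULL, n_permutations = 10000,
                         seed = 1L, q = NULL, n_resamples = 50, g_s = NULL,
                         alpha = 0.05) {
  stopifnot(inherits(x, "gene_lineage_matrix"))
  k <- ncol(x$values)
  chyper <- mean_pairwise_c_hyper(x, threshold = threshold)
  cchisq <- c_chisq(x, n_permutations = n_permutations, seed = seed)
  hyper_p <- if (k == 2) {
    cts <- pairwise_counts(x, 1, 2, threshold = threshold)
    tryCatch(hypergeom_pvalue(cts), error = function(e) NA_real_)
  } else NA_real_
  occ <- occupancy(x, threshold = threshold)
  ga_lik <- tryCatch(mle_ga(occ), error = function(e) NULL)
  ga_hyp <- if (k == 2) {
    cts <- pairwise_counts(x, 1, 2, threshold = threshold)
    tryCatch(ga_hat_hyper(cts), error = function(e) NULL)
  } else NULL
  sim <- similarity_indices(x, threshold = threshold)
  adj <- NULL
  if (!is.null(q)) {
    adj <- list(q = q)
    if (k == 2) {
      cts <- pairwise_counts(x, 1, 2, threshold = threshold)
      adj$c_hyper_adj <- suppressWarnings(c_hyper_adj(cts, q))
    }
    cadj <- c_chisq_adj(x, q, n_resamples = n_resamples,
                        n_permutations = n_permutations,
                        seed = derive_seed(seed, 99L))
    adj$c_chisq_adj <- cadj$c_score
    adj$c_chisq_adj_sd <- attr(cadj, "resample_sd")
    adj$n_resamples <- attr(cadj, "n_resamples")
  }
  interp <- interpret_constraints(
    p_ns = cchisq$p_value,
    p_gs = NULL, n_s = x$g0, g_s = g_s,
    ga_s = if (!is.null(ga_lik)) ga_lik$ga_s_hat else NA_real_,
    alpha = alpha)
  structure(list(
    n_genes = nrow(x$values), n_lineages = k, g0 = x$g0, mode = x$mode,
    parameters = list(threshold = threshold, n_permutations = n_permutations,
                      seed = seed, q = q, n_resamples = n_resamples,
                      alpha = alpha),
    c_hyper = chyper$c_score,
    hypergeom_p = hyper_p,
    c_chisq = cchisq$c_score,
    permutation_p = cchisq$p_value,
    null_mean = cchisq$null_mean, null_sd = cchisq$null_sd,
    ga_likelihood = if (!is.null(ga_lik)) ga_lik$ga_s_hat else NA_real_,
    pa_likelihood = if (!is.null(ga_lik)) ga_lik$pa_hat else NA_real_,
    ga_hypergeometric = if (!is.null(ga_hyp)) ga_hyp$ga_s_hat else NA_real_,
    pa_hypergeometric = if (!is.null(ga_hyp)) ga_hyp$pa_hat else NA_real_,
    similarity = as.list(attr(sim, "means")),
    adjusted = adj,
    interpretation = interp),
    class = "constraint_report")
}

#' @export
print.constraint_report <- function(x, ...) {
  cat(sprintf("Repeatability analysis: %d genes x %d lineages (%s), g0 = %d\n",
              x$n_genes, x$n_lineages, x$mode, x$g0))
  fmt <- function(v) if (is.na(v)) "undefined" else format(v, digits = 4)
  cat("  C_hyper (mean pairwise)  :", fmt(x$c_hyper), "\n")
  if (!is.na(x$hypergeom_p))
    cat("  hypergeometric p         :", fmt(x$hypergeom_p), "\n")
  cat("  C_chisq (mean pairwise)  :", fmt(x$c_chisq), "\n")
  p <- if (!is.na(x$permutation_p) && x$permutation_p == 0)
    sprintf("< %g", 1 / x$parameters$n_permutations) else fmt(x$permutation_p)
  cat("  permutation p            :", p, "\n")
  cat("  ga_s (likelihood)        :", fmt(x$ga_likelihood),
      sprintf("(Pa = %s)", fmt(x$pa_likelihood)), "\n")
  if (!is.na(x$ga_hypergeometric))
    cat("  ga_s (hypergeometric)    :", fmt(x$ga_hypergeometric),
        sprintf("(Pa = %s)", fmt(x$pa_hypergeometric)), "\n")
  cat(sprintf("  Jaccard %.3f | PS_add %.3f | PS_mult %.3f (pairwise means)\n",
              x$similarity$jaccard, x$similarity$ps_add, x$similarity$ps_mult))
  if (!is.null(x$adjusted)) {
    cat(sprintf("  sampling-adjusted (q = %.3f):", x$adjusted$q))
    if (!is.null(x$adjusted$c_hyper_adj))
      cat(" C_hyper_adj =", fmt(x$adjusted$c_hyper_adj), "|")
    cat(sprintf(" C_chisq_adj = %s +/- %s (%d resamples)\n",
                fmt(x$adjusted$c_chisq_adj), fmt(x$adjusted$c_chisq_adj_sd),
                x$adjusted$n_resamples))
  }
  cat("  interpretation:", x$interpretation, "\n")
  invisible(x)
}

#' Write a report as JSON
#'
#' @param report a `constraint_report` from [run_analysis()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "constraint_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

#' Interpret repeatability tests as diversity-constraint inferences
#'
#' Translates the outcome of the null-hypothesis tests into the standard
#' inference about GT-redundancy (how many gene combinations produce the
#' trait) and GF-redundancy (how many of those are equally fit). "Consistent
#' with the null" is operationalized as failing to reject at level `alpha`.
#' Without an independent estimate of the mutational-target size g_s, the
#' relative importance of GT- vs GF-redundancy cannot be evaluated and a
#' caveat is returned.
#'
#' @param p_ns p-value of the repeatability test under the no-constraint null
#'   (g0 = n_s).
#' @param p_gs p-value under the GT-redundancy null (g0 = g_s), or `NULL`.
#' @param n_s shared genome size.
#' @param g_s independent mutational-target size, or `NULL` when unknown.
#' @param ga_s estimated effective adaptive target (reported in the text).
#' @param alpha significance level.
#' @param eq_tol relative tolerance under which n_s and g_s are treated as
#'   equivalent.
#' @return a single interpretation string.
#' @export
interpret_constraints <- function(p_ns, p_gs = NULL, n_s = NA, g_s = NULL,
                                  ga_s = NA, alpha = 0.05, eq_tol = 0.05) {
  if (is.null(g_s) || is.null(p_gs)) {
    base <- if (!is.na(p_ns) && p_ns < alpha)
      paste0("Repeatability exceeds the no-constraint expectation ",
             "(p = ", format(p_ns, digits = 3), " < ", alpha,
             "): some diversity constraints are operating (ga_s < n_s)")
    else
      paste0("Repeatability is consistent with the no-constraint null ",
             "(p = ", format(p_ns, digits = 3), " >= ", alpha, ")")
    return(paste0(base, ". Without an independent estimate of the ",
                  "mutational-target size g_s it is not possible to evaluate ",
                  "the relative importance of GT- vs. GF-redundancy."))
  }
  ns_eq_gs <- g_s >= (1 - eq_tol) * n_s
  gs_eq_ga <- p_gs >= alpha
  if (ns_eq_gs && gs_eq_ga && !is.na(p_ns) && p_ns >= alpha)
    "No diversity constraints (High GT- and GF-redundancy)"
  else if (ns_eq_gs && !gs_eq_ga)
    "High GT-redundancy, low GF-redundancy"
  else if (!ns_eq_gs && !gs_eq_ga)
    "Low GT-redundancy, low GF-redundancy"
  else if (!ns_eq_gs && gs_eq_ga)
    "Low GT-redundancy, no additional contribution of low GF-redundancy"
  else  # ns_eq_gs, gs_eq_ga, but the no-constraint null was rejected
    "High GT-redundancy, low GF-redundancy"
}
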