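---
title: "Measuring constraints on the repeatability of adaptation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring constraints on the repeatability of adaptation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adaptrepeat)
```

## The question and the model

When independent lineages — replicate experimental populations, or species
adapting to the same environmental gradient — respond to the same selection
pressure, how often do they reuse the same genes, and what does that reuse
tell us about the constraints acting on adaptation? `adaptrepeat` works from a
gene-by-lineage matrix of adaptation evidence (binary "adapted" calls or
continuous scores such as F~ST~) and quantifies the excess of gene reuse over
what a null hypothesis predicts.

The central object is the gene universe g~0~: the number of genes that,
under the null being tested, are all equally available to adaptation. Testing
with g~0~ equal to the shared genome size n~s~ asks whether *any* constraint
is operating; testing with g~0~ equal to an independently estimated
mutational-target size g~s~ (the genes that can produce variation in the
trait) asks whether constraints *beyond* the genotype-to-trait map — e.g.
fitness differences among trait-equivalent genotypes — contribute additional
repeatability.

### Pairwise effect size

For two lineages with a~x~ and a~y~ adapted genes and a~s~ shared, the null
overlap is hypergeometric with mean a~x~a~y~/g~0~, and the effect size is the
z-score of the observed overlap:

$$C_{hyper} = \frac{a_s - a_x a_y / g_0}
  {\sqrt{a_x a_y (g_0 - a_x)(g_0 - a_y) / (g_0^2 (g_0 - 1))}}.$$

Because C is measured in null standard deviations it is comparable across
species and traits. `hypergeom_pvalue()` gives the exact upper-tail
probability P(X >= a~s~), inclusive per "a~s~ or more".

### Multiple lineages and continuous evidence

With k lineages, per-gene evidence totals o~i~ are compared to the equal-use
expectation e = (total evidence)/g~0~ through the dispersion statistic
chi^2 = sum (o~i~ - e)^2 / e over all g~0~ genes (implicit all-zero genes
included). Its null distribution is simulated by independently permuting each
lineage's scores across the universe; the p-value is the proportion of null
statistics at least as large as the observed one, and the effect size

$$C_{chisq} = \frac{\chi^2 - \overline{\chi^2_{sim}}}{sd(\chi^2_{sim})}$$

is averaged over lineage pairs (each with its own simulated null) so that it
measures per-bout repeatability and does not grow with the number of lineages
sampled, while the p-value comes from the simultaneous all-lineage test and
does gain power from every lineage. The same statistic accepts continuous
scores directly; `standardize_scores()` maps each lineage's scores onto
[0, 1] first (within-lineage by default, because evidence indices often
differ among lineages by orders of magnitude; global scaling is available
when between-lineage differences are meaningful, and either can be skipped).

We verified on simulated data that the two effect sizes are collinear
(Pearson r > 0.99 across datasets spanning no repeatability to complete
repeatability), so C_chisq extends the analytically exact C_hyper to
multi-lineage and continuous settings rather than measuring something
different.

### How many genes are effectively available to adaptation?

The occupancy histogram (how many genes are adapted in 0, 1, ..., k
lineages) identifies a two-class mixture: a fraction P~a~ = ga~s~/g~0~ of
genes belongs to the *effective adaptive target* and contributes in each
lineage independently with probability o-bar = sum(o~i~)/(ga~s~ k), the rest
never contribute. The probability of a gene's occupancy is

$$\zeta_i = P_a \,\mathrm{Bin}(k, \bar o, o_i) + (1 - P_a)\,\mathrm{Bin}(k, 0, o_i),$$

and `mle_ga()` maximizes the profile log-likelihood sum(log zeta~i~) over
integer ga~s~. Both mixture parameters are functions of ga~s~, so the
optimization is one-dimensional: an exhaustive integer grid when the search
interval holds at most 1e5 values (covering every dataset a genome scan
produces), otherwise golden-section search with an integer neighborhood
check. The lower search bound is max(ceiling(sum(o)/k), number of genes ever
observed adapted): the first term keeps o-bar <= 1, and the second encodes
that every observed adapted gene must belong to the target — implied by the
model though easy to overlook. A closed-form pairwise estimator
(`ga_hat_hyper()`, ga~s~ = a~x~a~y~/a~s~) complements the MLE but is
undefined when a~s~ = 0, which is precisely why the likelihood route exists.

The mixture assumes all target genes are equally likely to contribute. When
that is badly violated — one gene adapting in every lineage among many
low-probability genes — the estimate gravitates toward the repeatable class
and *underestimates* the true target size; the test suite constructs such a
case and asserts the direction of the distortion.

## Tunable parameters

* **g0** (genes): the null universe. The single most consequential choice;
  it is data, not a tuning knob, and every result should state it.
* **threshold** (score units): binarization cutoff for continuous data,
  applied as score > threshold (strict), e.g. "adapted if F_ST > 0.1".
* **n_permutations** (default 10,000): permutation replicates per null.
  The p-value granularity is 1/n; the default matches common practice for
  genome-scale scans and the worked examples. p = 0 is printed as
  "< 1/n". An inclusive tie rule (>=) is the default because discrete data
  produce massive ties; `strict_greater = TRUE` restores the strict rule,
  and `add_one = TRUE` the (b+1)/(B+1) estimator.
* **q** (fraction in (0, 1]): the sampled fraction of the gene universe.
  `c_hyper_adj()` divides all four inputs by q (exact algebra);
  `c_chisq_adj()` rebuilds the unsampled genes by resampling whole gene rows
  with replacement (default 50 replicates, matching the worked example),
  keeping each gene's cross-lineage profile intact — resampling columns
  independently would destroy the repeatability signal being corrected. The
  number of appended rows, round(G(1 - q)) with G = round(g0/q), uses
  nearest-integer rounding.
* **seed**: all stochastic routines take one and restore the caller's RNG
  state; per-pair and per-replicate sub-seeds are derived deterministically
  from it, so results are bit-for-bit reproducible.

## The synthetic-data generators

`generate_sorted_pair()` reproduces the standard benchmark for repeatability
indices: two lineages with a and a + 20 adapted genes placed uniformly among
g~s~ = 200 genes, with a chosen proportion of rows sorted so that adapted
genes co-occur — a dial from chance overlap (proportion 0) to forced overlap
(proportion 1). It is used to verify the C_hyper/C_chisq collinearity and the
sampling corrections.

`simulate_two_patch()` is a minimal individual-based model of local
adaptation under migration-selection balance: two patches of N diploids with
optima +1 and -1, an additive trait controlled by biallelic loci of effect
+/-0.1 (large) or +/-0.01 (small), Gaussian viability selection with width
calibrated so a perfect resident has fitness 0.5 at the opposite optimum,
random mating within patches, free recombination, sign-flip mutation, and
symmetric migration (default m = 0.005). Per-locus F~ST~ (a G~ST~-type
1 - H~S~/H~T~ estimator, the conventional choice where the estimator is
otherwise unspecified; it is isolated in `fst()` so alternatives can be
swapped) is censused at fixed intervals, and `classify_adapted()` calls a
locus adapted when F~ST~ > 0.1 in strictly more than 80% of the last 25
censuses. Under these dynamics large-effect alleles resist swamping by gene
flow while small-effect alleles cannot — a fitness-map constraint invisible
to similarity indices: as small-effect loci are added, Jaccard and PS stay
flat while C-scores rise and the estimated available fraction of the genome
falls. Individuals are diploid and start monomorphic with allele signs drawn
at random per locus.

What the generators do *not* emulate: linkage and genetic maps, demographic
structure beyond two patches, heterogeneous mutation rates, shared standing
variation, correlated false positives from conserved recombination
landscapes. Tests passing on these inputs show the statistics behave as
designed under their own assumptions, not that real genome scans are free of
those confounders — on real data, shared standing variation and structured
false positives can inflate or deflate C-scores in ways no within-dataset
statistic can detect.

## Numerical choices and degenerate inputs

* C_hyper is undefined (zero null SD) when a lineage has 0 or g~0~ adapted
  genes; such pairs return `NA` with a warning and are *excluded* from the
  multi-lineage mean — zero-filling would bias toward "no constraint".
* The chi-square permutation engine works on the sparse representation
  (each lineage's nonzero scores scattered over 1..g~0~) and the identity
  sum((r - e)^2)/e = sum(r^2)/e - S, so universes of tens of thousands of
  genes cost only the nonzero entries per replicate.
* Under permutation with fixed within-lineage totals the null mean of the
  binary statistic is g~0~ - a (finite-population sampling), which
  approaches the analytic df = g~0~ - 1 only when each lineage adapts a
  small fraction of the universe — one reason the package simulates the null
  rather than using the analytic chi-square distribution, whose tail is also
  unreliable at the low expected counts (e << 1) typical of genome scans.
* Likelihood boundary: at ga~s~ = sum(o)/k the within-target rate is
  o-bar = 1 and any intermediate occupancy has probability zero; the profile
  log-likelihood returns -Inf there rather than an error so the grid search
  can traverse it.
* `mle_ga()` reports an integer; the worked-example optimum is insensitive
  to +/-1 grid steps and the test tolerance (2 genes) reflects optimizer
  granularity only.

## Problem sizes used in the test suite

The suite favors exact desk-scale recomputation of the worked examples
(universes of 4-9891 genes, 10^5 permutations where a printed p-value is
checked) and reduced-scale versions of the simulation studies: the
two-patch sweeps use N = 1000 per patch, 600 generations and mutation rate
5e-4 (scaled up from the long-run setting so migration-selection balance is
reached quickly at small N while 4Nm stays large enough to keep neutral
F~ST~ below the adapted cutoff), 4 lineages per configuration; the sampling
sweep uses a 500-locus concatenated high-repeatability dataset with 6
subsample replicates per q and 10 resampling replicates each. These sizes
are the package's chosen balance between statistical resolution of the
qualitative claims and quick iteration; all are ordinary function arguments,
so paper-scale runs (N = 10,000, 50,000 generations) are a config change.

## Known limitations

* The equal-probability mixture behind `mle_ga()` is a single-class model;
  heterogeneous contribution probabilities bias it (documented direction
  above). Multi-class extensions are out of scope.
* Unequal gene content between lineages (n~x~ != n~y~) is not modeled; the
  statistics assume a shared universe, appropriate for recently diverged
  lineages or one-to-one ortholog sets.
* The q-correction assumes the sampled genes are a random subset of the
  universe; targeted capture designs enriched for candidate genes violate
  this and will overcorrect.
* No lower-tail "less overlap than expected" test is provided beyond the
  sign of C; negative scores are reported as such.
* The two-patch simulator is not a general population-genetics engine: no
  linkage maps, selfing, stage structure, or distributions of effect sizes.
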