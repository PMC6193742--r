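#' Worked-example data: first-step nystatin adaptation in yeast
#'
#' Twenty replicate yeast lines evolved on the antifungal nystatin from an
#' isogenic ancestor each acquired a single first-step adaptive mutation, in
#' only four genes of the ergosterol pathway: 11 lines mutated ERG3, 7 ERG6,
#' and one line each ERG5 and ERG7. Returned as a 4-gene x 20-lineage binary
#' matrix. The gene universe depends on the hypothesis: g0 = 6604 (all yeast
#' genes; no-constraint null) or g0 = 4 (only the observed genes can mutate;
#' severe GT-constraint null).
#'
#' @param g0 gene-universe size (default 6604, the yeast gene count).
#' @return a binary [gene_lineage_matrix()].
#' @export
yeast_nystatin_matrix <- function(g0 = 6604) {
  path <- system.file("extdata", "yeast_nystatin.tsv", package = "adaptrepeat")
  read_matrix(path, mode = "binary", g0 = g0)
}

#' Worked-example data: cold-tolerance candidate-gene overlap in conifers
#'
#' Genotype-environment association scans in lodgepole pine and interior
#' spruce identified top-candidate genes for Mean Coldest Month Temperature
#' (MCMT) among 9891 one-to-one orthologs: 50 candidates in pine and 121 in
#' spruce, 5 of them shared. The annual heat-moisture (AHM) contrasts serve
#' as negative controls: 23 spruce-AHM candidates overlap pine-MCMT in 1
#' gene; 25 pine-AHM candidates overlap spruce-MCMT in 0.
#'
#' @param contrast which published contrast to return.
#' @return a `pairwise_counts` object.
#' @export
conifer_counts <- function(contrast = c("mcmt", "ahm_spruce_vs_pine_mcmt",
                                        "ahm_pine_vs_spruce_mcmt")) {
  contrast <- match.arg(contrast)
  path <- system.file("extdata", "conifer_counts.tsv", package = "adaptrepeat")
  tab <- utils::read.table(path, header = TRUE, sep = "\t")
  row <- tab[tab$contrast == contrast, ]
  pairwise_counts_from(row$a_x, row$a_y, row$a_s, row$g0)
}

#' Conifer MCMT occupancy histogram
#'
#' The two-lineage occupancy counts implied by the MCMT contrast: 5 genes
#' adapted in both species, (50 - 5) + (121 - 5) = 161 in exactly one, and
#' 9891 - 166 = 9725 in neither. Input for [mle_ga()].
#'
#' @return an `occupancy_counts` object with k = 2, g0 = 9891.
#' @export
conifer_occupancy <- function() {
  cc <- conifer_counts("mcmt")
  singles <- (cc$a_x - cc$a_s) + (cc$a_y - cc$a_s)
  occupancy_counts(c("2" = cc$a_s, "1" = singles,
                     "0" = cc$g0 - cc$a_s - singles),
                   k = 2, g0 = cc$g0)
}
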