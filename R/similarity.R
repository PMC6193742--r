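#' Jaccard index of adapted-gene overlap
#'
#' |intersection| / |union| of the adapted-gene sets of two lineages. A pure
#' repeatability index: unlike the C-scores it carries no information about
#' the genes that could have contributed but did not, so it is insensitive to
#' the size of the gene universe.
#'
#' @param x,y binary vectors of equal length (nonzero = adapted).
#' @return a number in [0, 1], or `NA` with a warning when both sets are
#'   empty.
#' @export
jaccard <- function(x, y) {
  check_pair(x, y)
  xs <- x > 0; ys <- y > 0
  u <- sum(xs | ys)
  if (u == 0) {
    warning("Jaccard undefined: both adapted-gene sets are empty")
    return(NA_real_)
  }
  sum(xs & ys) / u
}

#' Additive proportional similarity
#'
#' PS_add = sum_i min(x_i, y_i) after each vector is normalized to relative
#' contributions (divided by its sum). Equals 1 for identical contribution
#' distributions and 0 for disjoint support.
#'
#' @param x,y non-negative score vectors of equal length with positive sums.
#' @return a number in [0, 1].
#' @export
ps_add <- function(x, y) {
  check_pair(x, y)
  if (sum(x) <= 0 || sum(y) <= 0)
    stop("PS_add requires vectors with positive sums")
  sum(pmin(x / sum(x), y / sum(y)))
}

#' Multiplicative proportional similarity
#'
#' PS_mult = sum(x_i y_i) / sqrt(sum(x_i^2) sum(y_i^2)): the cosine
#' similarity of the two score vectors. Invariant to positive rescaling of
#' either vector.
#'
#' @param x,y non-negative score vectors of equal length, each with at least
#'   one positive value.
#' @return a number in [0, 1].
#' @export
ps_mult <- function(x, y) {
  check_pair(x, y)
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) stop("PS_mult requires non-zero vectors")
  sum(x * y) / (nx * ny)
}

#' All pairwise similarity indices for a matrix
#'
#' Computes [jaccard()], [ps_add()] and [ps_mult()] for every unordered pair
#' of lineages, plus their means. For continuous matrices Jaccard is computed
#' on supports binarized at `threshold`; the PS indices use the scores as
#' given.
#'
#' @inheritParams pairwise_counts
#' @return a data frame with one row per lineage pair and columns
#'   `lineage_x`, `lineage_y`, `jaccard`, `ps_add`, `ps_mult`, plus an
#'   attribute `means` with the column means.
#' @export
similarity_indices <- function(x, threshold = NULL) {
  stopifnot(inherits(x, "gene_lineage_matrix"))
  k <- ncol(x$values)
  if (k < 2) stop("need at least two lineages")
  pairs <- utils::combn(k, 2)
  out <- data.frame(lineage_x = x$lineage_ids[pairs[1, ]],
                    lineage_y = x$lineage_ids[pairs[2, ]],
                    jaccard = NA_real_, ps_add = NA_real_, ps_mult = NA_real_)
  for (p in seq_len(ncol(pairs))) {
    vx <- x$values[, pairs[1, p]]
    vy <- x$values[, pairs[2, p]]
    bx <- as.numeric(binarize_column(x, pairs[1, p], threshold))
    by <- as.numeric(binarize_column(x, pairs[2, p], threshold))
    out$jaccard[p] <- suppressWarnings(jaccard(bx, by))
    out$ps_add[p] <- ps_add(vx, vy)
    out$ps_mult[p] <- ps_mult(vx, vy)
  }
  attr(out, "means") <- colMeans(out[, c("jaccard", "ps_add", "ps_mult")],
                                 na.rm = TRUE)
  out
}

check_pair <- function(x, y) {
  if (length(x) != length(y)) stop("vectors must have equal length")
  if (any(x < 0) || any(y < 0)) stop("scores must be non-negative")
  invisible(TRUE)
}
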