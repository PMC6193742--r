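#' Gene-by-lineage evidence matrices
#'
#' A `gene_lineage_matrix` holds per-gene, per-lineage evidence of adaptation:
#' either a binary classification (1 = adapted, 0 = non-adapted) or a
#' continuous non-negative score (e.g. F_ST, -log p, top-candidate index).
#' Only genes with some recorded evidence need to be listed; the gene universe
#' under the null hypothesis may be larger, so `g0 >= nrow(values)` and genes
#' without a row are treated as all-zero. `g0` carries whichever universe the
#' hypothesis under test requires: the shared genome size n_s for the
#' no-constraint null, or the mutational-target size g_s for the
#' GT-redundancy null.
#'
#' @param values numeric matrix of non-negative finite scores, genes in rows,
#'   lineages in columns.
#' @param gene_ids character vector of unique gene identifiers (defaults to
#'   rownames of `values`).
#' @param lineage_ids character vector of unique lineage identifiers (defaults
#'   to colnames of `values`).
#' @param g0 size of the gene universe under the null; defaults to
#'   `nrow(values)`.
#' @param mode `"binary"` or `"continuous"`.
#'
#' @return an object of class `gene_lineage_matrix` with elements `values`,
#'   `gene_ids`, `lineage_ids`, `g0` and `mode`.
#' @seealso [read_matrix()], [pairwise_counts()], [occupancy()]
#' @export
gene_lineage_matrix <- function(values, gene_ids = rownames(values),
                                lineage_ids = colnames(values),
                                g0 = nrow(values),
                                mode = c("binary", "continuous")) {
  mode <- match.arg(mode)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(nrow(values)))
  if (is.null(lineage_ids)) lineage_ids <- paste0("lineage", seq_len(ncol(values)))
  gene_ids <- as.character(gene_ids)
  lineage_ids <- as.character(lineage_ids)
  if (length(gene_ids) != nrow(values))
    stop("length(gene_ids) must equal nrow(values)")
  if (length(lineage_ids) != ncol(values))
    stop("length(lineage_ids) must equal ncol(values)")
  if (anyDuplicated(gene_ids))
    stop("duplicate gene ids: ", paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  if (anyDuplicated(lineage_ids))
    stop("duplicate lineage ids: ", paste(unique(lineage_ids[duplicated(lineage_ids)]), collapse = ", "))
  if (!is_count(g0) || g0 < 1) stop("g0 must be a positive integer")
  if (g0 < nrow(values))
    stop("g0 (", g0, ") is smaller than the number of genes (", nrow(values), ")")
  if (any(!is.finite(values)))
    stop("scores must be finite")
  if (any(values < 0))
    stop("negative score at gene ", gene_ids[which(values < 0, arr.ind = TRUE)[1, 1]])
  if (mode == "binary" && !all(values %in% c(0, 1)))
    stop("binary mode requires all scores in {0, 1}")
  dimnames(values) <- list(gene_ids, lineage_ids)
  structure(list(values = values, gene_ids = gene_ids,
                 lineage_ids = lineage_ids, g0 = as.integer(g0), mode = mode),
            class = "gene_lineage_matrix")
}

#' @export
print.gene_lineage_matrix <- function(x, ...) {
  cat(sprintf("gene_lineage_matrix: %d genes x %d lineages (%s), g0 = %d\n",
              nrow(x$values), ncol(x$values), x$mode, x$g0))
  cat(sprintf("  total evidence: %g; genes with any evidence: %d\n",
              sum(x$values), sum(rowSums(x$values) > 0)))
  invisible(x)
}

#' @export
dim.gene_lineage_matrix <- function(x) dim(x$values)

#' Read a gene-by-lineage matrix from delimited text
#'
#' Expects a header row of lineage identifiers, a first column of gene
#' identifiers and one gene per row. The delimiter is inferred from the file
#' extension (`.csv` = comma, otherwise tab) unless given explicitly.
#'
#' @param path path to a TSV/CSV file.
#' @param mode `"binary"` or `"continuous"`.
#' @param g0 gene-universe size; defaults to the number of rows in the file.
#' @param sep field delimiter; `NULL` to infer from the extension.
#' @return a [gene_lineage_matrix()].
#' @export
read_matrix <- function(path, mode = c("binary", "continuous"), g0 = NULL,
                        sep = NULL) {
  mode <- match.arg(mode)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          colClasses = "character", quote = "")
  if (ncol(df) < 2) stop("matrix file needs a gene column plus >= 1 lineage column")
  gene_ids <- df[[1]]
  vals <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop(sprintf("malformed numeric cell at gene '%s', lineage '%s'",
                 gene_ids[bad[1]], colnames(vals)[bad[2]]))
  }
  colnames(num) <- colnames(vals)
  gene_lineage_matrix(num, gene_ids = gene_ids, lineage_ids = colnames(vals),
                      g0 = g0 %||% nrow(num), mode = mode)
}

#' Write a gene-by-lineage matrix as tab-separated text
#'
#' Writes the explicit rows only (implicit all-zero genes up to `g0` are not
#' materialized); `g0` and `mode` are the caller's responsibility to record,
#' e.g. in a config file.
#'
#' @param x a [gene_lineage_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(x, path) {
  stopifnot(inherits(x, "gene_lineage_matrix"))
  df <- data.frame(gene = x$gene_ids, x$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Adapted-gene counts for a pair of lineages
#'
#' Counts the adapted genes in each of two lineages (`a_x`, `a_y`), the genes
#' adapted in both (`a_s`), and carries the gene-universe size `g0`. For
#' continuous matrices a threshold must be supplied; a gene is adapted when
#' its score is strictly greater than the threshold.
#'
#' @param x a binary [gene_lineage_matrix()], or a continuous one with
#'   `threshold`.
#' @param lineage_x,lineage_y lineage identifiers (or column indices).
#' @param threshold binarization cutoff for continuous matrices
#'   (score > threshold means adapted).
#' @return a `pairwise_counts` object; see [pairwise_counts_from()] to build
#'   one directly from published counts.
#' @export
pairwise_counts <- function(x, lineage_x, lineage_y, threshold = NULL) {
  stopifnot(inherits(x, "gene_lineage_matrix"))
  cx <- resolve_lineage(x, lineage_x)
  cy <- resolve_lineage(x, lineage_y)
  if (x$mode == "binary" && !is.null(threshold)) {
    warning("threshold ignored for a binary matrix")
    threshold <- NULL
  }
  vx <- binarize_column(x, cx, threshold)
  vy <- binarize_column(x, cy, threshold)
  pairwise_counts_from(a_x = sum(vx), a_y = sum(vy), a_s = sum(vx & vy),
                       g0 = x$g0)
}

#' Construct pairwise counts directly
#'
#' @param a_x,a_y number of adapted genes in each lineage.
#' @param a_s number of genes adapted in both.
#' @param g0 gene-universe size.
#' @return a `pairwise_counts` object.
#' @export
pairwise_counts_from <- function(a_x, a_y, a_s, g0) {
  for (v in list(a_x, a_y, a_s, g0))
    if (!(is.numeric(v) && length(v) == 1L && is.finite(v) && v >= 0))
      stop("counts must be single non-negative finite numbers")
  if (g0 <= 0) stop("g0 must be positive")
  if (a_s > min(a_x, a_y) + 1e-9)
    stop("a_s cannot exceed min(a_x, a_y)")
  if (a_x > g0 || a_y > g0) stop("a_x and a_y cannot exceed g0")
  if (a_s < max(0, a_x + a_y - g0) - 1e-9)
    stop("a_s below the feasible minimum max(0, a_x + a_y - g0)")
  structure(list(a_x = as.double(a_x), a_y = as.double(a_y),
                 a_s = as.double(a_s), g0 = as.double(g0)),
            class = "pairwise_counts")
}

#' @export
print.pairwise_counts <- function(x, ...) {
  cat(sprintf("pairwise_counts: a_x = %g, a_y = %g, a_s = %g, g0 = %g\n",
              x$a_x, x$a_y, x$a_s, x$g0))
  invisible(x)
}

#' Lineage-occupancy histogram
#'
#' For each gene, the occupancy o_i is the number of lineages in which it is
#' classified as adapted. This returns the histogram of o over the full
#' g0-gene universe (genes absent from the matrix count as o = 0), the input
#' to the adaptive-target likelihood.
#'
#' @inheritParams pairwise_counts
#' @return an `occupancy_counts` object with elements `counts` (named integer
#'   vector over o = 0..k), `k` and `g0`.
#' @export
occupancy <- function(x, threshold = NULL) {
  stopifnot(inherits(x, "gene_lineage_matrix"))
  k <- ncol(x$values)
  bin <- vapply(seq_len(k), function(j) binarize_column(x, j, threshold),
                logical(nrow(x$values)))
  if (nrow(x$values) == 0L) bin <- matrix(FALSE, 0, k)
  o <- if (nrow(x$values)) rowSums(bin) else integer(0)
  counts <- tabulate(o + 1L, nbins = k + 1L)
  counts[1L] <- counts[1L] + (x$g0 - nrow(x$values))
  occupancy_counts(stats::setNames(counts, 0:k), k = k, g0 = x$g0)
}

#' Construct an occupancy histogram directly
#'
#' @param counts named vector mapping occupancy values (0..k) to gene counts;
#'   occupancies not named are taken as zero.
#' @param k number of lineages.
#' @param g0 gene-universe size; `sum(counts)` must equal `g0`.
#' @return an `occupancy_counts` object.
#' @export
occupancy_counts <- function(counts, k, g0) {
  if (!is_count(k) || k < 1) stop("k must be a positive integer")
  if (!is_count(g0)) stop("g0 must be a non-negative integer")
  full <- stats::setNames(numeric(k + 1), 0:k)
  if (is.null(names(counts))) {
    if (length(counts) != k + 1)
      stop("unnamed counts must have length k + 1 (o = 0..k)")
    names(counts) <- 0:k
  }
  o <- as.integer(names(counts))
  if (anyNA(o) || any(o < 0 | o > k)) stop("occupancy values must lie in 0..k")
  if (any(counts < 0) || any(counts != floor(counts)))
    stop("counts must be non-negative integers")
  full[as.character(o)] <- counts
  if (sum(full) != g0)
    stop("sum(counts) = ", sum(full), " must equal g0 = ", g0)
  structure(list(counts = full, k = as.integer(k), g0 = as.integer(g0)),
            class = "occupancy_counts")
}

#' @export
print.occupancy_counts <- function(x, ...) {
  cat(sprintf("occupancy_counts over %d lineages, g0 = %d genes\n", x$k, x$g0))
  print(x$counts)
  invisible(x)
}

resolve_lineage <- function(x, id) {
  if (is.numeric(id)) {
    if (!is_count(id) || id < 1 || id > ncol(x$values))
      stop("lineage index out of range: ", id)
    return(as.integer(id))
  }
  j <- match(as.character(id), x$lineage_ids)
  if (is.na(j)) stop("unknown lineage id: ", id)
  j
}

binarize_column <- function(x, j, threshold) {
  v <- x$values[, j]
  if (x$mode == "binary") {
    if (!is.null(threshold))
      warning("threshold ignored for a binary matrix")
    return(v > 0)
  }
  if (is.null(threshold))
    stop("a threshold is required to binarize a continuous matrix")
  v > threshold
}
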