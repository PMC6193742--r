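# shared generators for test matrices

# binary matrix with each lineage adapting `a` genes uniformly (no induced
# repeatability beyond chance)
random_binary_matrix <- function(g0, k, a, seed) {
  v <- adaptrepeat:::with_seed(seed, {
    m <- matrix(0, g0, k)
    for (j in seq_len(k)) m[sample.int(g0, a), j] <- 1
    m
  })
  gene_lineage_matrix(v, g0 = g0, mode = "binary")
}

# concatenation of sorted-pair blocks into one high-repeatability dataset
concat_sorted_blocks <- function(n_blocks, g_s, a_small, a_offset,
                                 sort_proportion, seed) {
  blocks <- lapply(seq_len(n_blocks), function(b)
    generate_sorted_pair(g_s, a_small, a_offset, sort_proportion,
                         seed = seed * 100 + b)$values)
  v <- do.call(rbind, blocks)
  gene_lineage_matrix(v, gene_ids = paste0("g", seq_len(nrow(v))),
                      g0 = nrow(v), mode = "binary")
}

# occupancy histogram drawn from the homogeneous generative model:
# ga of g0 genes each contribute independently in each of k lineages
# with probability obar
simulate_occupancy <- function(g0, ga, k, obar, seed) {
  adaptrepeat:::with_seed(seed, {
    o <- stats::rbinom(ga, k, obar)
    counts <- tabulate(o + 1L, nbins = k + 1L)
    counts[1L] <- counts[1L] + (g0 - ga)
    occupancy_counts(stats::setNames(counts, 0:k), k = k, g0 = g0)
  })
}
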