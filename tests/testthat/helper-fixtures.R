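# Shared fixture builders for the test suite. Everything is generated in
# code under fixed seeds; no data files are read.

# Small two-population cohort config (fast paths).
small_cohort <- function(n_samples = 2, n_events = 600, seed = 42L) {
  phenotime::generate_event_cohort(
    phenotime::default_cohort_config(n_samples = n_samples,
                                     n_events = n_events, seed = seed))
}

# A pheno_graph from an explicit edge list (unit weights by default).
graph_from_edges <- function(n, from, to, weight = rep(1, length(from))) {
  structure(list(n_nodes = as.integer(n), k = NA_integer_,
                 edges = data.frame(from = from, to = to, weight = weight)),
            class = "pheno_graph")
}

# Two disjoint triangles on 6 nodes.
two_triangles <- function() {
  graph_from_edges(6, c(1, 2, 1, 4, 5, 4), c(2, 3, 3, 5, 6, 6))
}

# Complete graph K4.
k4_graph <- function() {
  pairs <- t(combn(4, 2))
  graph_from_edges(4, pairs[, 1], pairs[, 2])
}

# Random Erdos-Renyi graph on n nodes (possibly with isolated nodes).
random_small_graph <- function(n, p, seed) {
  pairs <- t(combn(n, 2))
  keep <- phenotime:::with_seed(seed, runif(nrow(pairs)) < p)
  graph_from_edges(n, pairs[keep, 1], pairs[keep, 2])
}

# Adjusted Rand index between two labelings (mclust is the oracle).
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# Two well-separated Gaussian blobs as a transformed event table.
two_blob_table <- function(n_per = 150, sep = 10, d = 3, seed = 5L) {
  m <- phenotime:::with_seed(seed, {
    rbind(matrix(rnorm(n_per * d, 0, 1), ncol = d),
          matrix(rnorm(n_per * d, sep, 1), ncol = d))
  })
  colnames(m) <- paste0("ch", seq_len(d))
  tb <- phenotime::event_table(m, "blobs", transform_state = "arcsinh",
                               transform_params = list(note = "synthetic"))
  tb
}

# Log2-scale expression matrix with the full normalization flags attached.
log2_expr <- function(values) {
  phenotime::expression_matrix(values, norm_state = c("tpm", "quantile", "log2"))
}
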