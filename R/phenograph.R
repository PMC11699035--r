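#' Build a Jaccard-weighted k-nearest-neighbour graph
#'
#' Exact Euclidean k-NN per event (ties broken by row index), converted to an
#' undirected edge set in which each edge is weighted by the Jaccard
#' coefficient of the two endpoints' k-neighbour sets.  Edges with zero
#' Jaccard overlap are pruned, following the PhenoGraph construction.
#'
#' @param events a transformed [event_table()], or a plain numeric matrix.
#' @param k neighbour count (must be smaller than the number of events).
#' @param metric distance metric; only `"euclidean"` is implemented.
#' @param channels channels to use (default: all).
#' @return a `pheno_graph`: node count, `k`, and a `data.frame` of weighted
#'   undirected edges (`from < to`, weights in (0, 1]).
#' @export
build_knn_graph <- function(events, k = 60, metric = "euclidean",
                            channels = NULL) {
  metric <- match.arg(metric, "euclidean")
  m <- if (inherits(events, "event_table")) {
    if (events$transform_state == "raw")
      stop("build_knn_graph expects a transformed table")
    if (is.null(channels)) channels <- events$channels
    events$values[, channels, drop = FALSE]
  } else {
    as.matrix(events)
  }
  if (k >= nrow(m)) stop("k must be smaller than the number of events")
  nn <- cpp_knn(m, as.integer(k))
  edges <- cpp_jaccard_edges(nn)
  structure(list(n_nodes = nrow(m), k = as.integer(k), edges = edges),
            class = "pheno_graph")
}

#' @export
print.pheno_graph <- function(x, ...) {
  cat(sprintf("pheno_graph: %d nodes, %d edges%s\n", x$n_nodes, nrow(x$edges),
              if (is.na(x$k)) "" else sprintf(" (k = %d)", x$k)))
  invisible(x)
}

#' Louvain community detection on a weighted graph
#'
#' From-scratch weighted Louvain modularity optimization: greedy local moves
#' and community aggregation, alternated with a fine-level refinement sweep
#' until neither level improves.  The node sweep order is a seeded
#' permutation; among equal-gain moves the lowest community id wins, so the
#' result is deterministic for a given seed.  For small graphs several
#' seeded restarts are run and the best-modularity partition kept, which in
#' practice reaches the global optimum on graphs of a few hundred nodes.
#'
#' @param g a `pheno_graph` (from [build_knn_graph()] or
#'   [generate_planted_graph()]).
#' @param resolution resolution parameter multiplying the null-model term
#'   (default 1).
#' @param seed integer seed for the sweep order.
#' @param n_restarts number of seeded restarts; default 10 for graphs of at
#'   most 2048 nodes, 1 above.
#' @return a `partition`: `labels` (integer communities, 1-based, relabeled
#'   by decreasing size) and `modularity`.
#' @export
louvain_partition <- function(g, resolution = 1, seed = 0L, n_restarts = NULL) {
  stopifnot(inherits(g, "pheno_graph"))
  if (g$n_nodes < 1) stop("graph is empty")
  if (is.null(n_restarts)) n_restarts <- if (g$n_nodes <= 2048) 10L else 1L
  if (nrow(g$edges) == 0) {
    return(structure(list(labels = seq_len(g$n_nodes), modularity = 0,
                          seed = seed, resolution = resolution),
                     class = "partition"))
  }
  best <- NULL
  for (r in seq_len(n_restarts)) {
    ord <- with_seed(derive_seed(seed, r), sample.int(g$n_nodes))
    res <- cpp_louvain(g$n_nodes, g$edges$from, g$edges$to, g$edges$weight,
                       resolution, ord)
    if (is.null(best) || res$modularity > best$modularity + 1e-12) best <- res
  }
  labels <- relabel_by_size(best$labels)
  structure(list(labels = labels, modularity = best$modularity,
                 seed = seed, resolution = resolution),
            class = "partition")
}

relabel_by_size <- function(labels) {
  tab <- sort(table(labels), decreasing = TRUE)
  map <- setNames(seq_along(tab), names(tab))
  as.integer(map[as.character(labels)])
}

#' Modularity of a labeled partition
#'
#' `Q = sum_c (e_c / m - gamma * (d_c / 2m)^2)` with weighted intra-community
#' edge sums `e_c`, weighted degrees `d_c` and total edge weight `m`.
#'
#' @param g a `pheno_graph`.
#' @param labels integer community labels per node.
#' @param resolution resolution parameter `gamma` (default 1).
#' @return scalar modularity.
#' @export
modularity_q <- function(g, labels, resolution = 1) {
  stopifnot(inherits(g, "pheno_graph"))
  if (length(labels) != g$n_nodes) stop("labels must cover all nodes")
  if (nrow(g$edges) == 0) return(0)
  cpp_modularity(g$n_nodes, g$edges$from, g$edges$to, g$edges$weight,
                 as.integer(factor(labels)), resolution)
}

#' Exhaustive best-modularity partition (small graphs)
#'
#' Brute-force search over all set partitions of the nodes; feasible up to
#' roughly 10 nodes (Bell(10) = 115,975).  Used as an independent oracle for
#' the Louvain optimizer.
#'
#' @param g a `pheno_graph` with few nodes.
#' @param resolution resolution parameter.
#' @return list with `labels` and `modularity` of the best partition found.
#' @export
best_partition_exact <- function(g, resolution = 1) {
  stopifnot(inherits(g, "pheno_graph"))
  n <- g$n_nodes
  if (n > 10) stop("exhaustive search is limited to 10 nodes")
  best_q <- -Inf
  best <- rep(1L, n)
  labels <- integer(n)
  recurse <- function(i, n_used) {
    if (i > n) {
      q <- modularity_q(g, labels[seq_len(n)], resolution)
      if (q > best_q) {
        best_q <<- q
        best <<- labels[seq_len(n)]
      }
      return(invisible(NULL))
    }
    for (c in seq_len(n_used + 1L)) {
      labels[i] <<- c
      recurse(i + 1L, max(n_used, c))
    }
  }
  recurse(1L, 0L)
  list(labels = best, modularity = best_q)
}

#' PhenoGraph-style clustering of events
#'
#' k-NN graph construction, Jaccard re-weighting and Louvain optimization in
#' one call.
#'
#' @inheritParams build_knn_graph
#' @inheritParams louvain_partition
#' @return a `partition` (labels relabeled by decreasing cluster size).
#' @export
phenograph <- function(events, k = 60, channels = NULL, resolution = 1,
                       seed = 0L) {
  g <- build_knn_graph(events, k = k, channels = channels)
  louvain_partition(g, resolution = resolution, seed = seed)
}

#' Two-round phenoclustering with CD45-low cluster filtering
#'
#' Round 1 clusters all merged events.  Clusters with low CD45 signal are
#' then removed with all their events — by default clusters whose median
#' CD45 falls strictly below the 25th percentile of per-cluster medians
#' (`cd45_mode = "quantile"`, a scale-free criterion for fluorescence data);
#' with `cd45_mode = "absolute"` an absolute threshold on the transformed
#' scale is used instead (e.g. 0.5 on the arcsinh scale for mass cytometry).
#' Surviving events are re-clustered in round 2.
#'
#' @param merged a transformed, merged [event_table()] (see
#'   [merge_samples()]).
#' @param k neighbour count (default 60).
#' @param cd45_channel name of the CD45 channel.
#' @param cd45_mode `"quantile"` or `"absolute"`.
#' @param cd45_threshold quantile level (default 0.25) or absolute threshold
#'   (default 0.5) depending on the mode.
#' @param channels channels used for clustering (default: all).
#' @param resolution Louvain resolution.
#' @param seed integer seed.
#' @return a `pheno_result`: `round1_labels`, `kept_mask`, `round2_labels`
#'   (NA outside the mask), per-round modularity, and the parameters used.
#' @export
two_round_cluster <- function(merged, k = 60, cd45_channel = "CD45",
                              cd45_mode = c("quantile", "absolute"),
                              cd45_threshold = NULL, channels = NULL,
                              resolution = 1, seed = 0L) {
  stopifnot_event_table(merged)
  cd45_mode <- match.arg(cd45_mode)
  if (!cd45_channel %in% merged$channels)
    stop("CD45 channel '", cd45_channel, "' not present")
  if (is.null(cd45_threshold))
    cd45_threshold <- if (cd45_mode == "quantile") 0.25 else 0.5

  round1 <- phenograph(merged, k = k, channels = channels,
                       resolution = resolution, seed = derive_seed(seed, 1L))
  cd45 <- merged$values[, cd45_channel]
  med <- tapply(cd45, round1$labels, median)
  cut <- if (cd45_mode == "quantile") quantile(med, cd45_threshold, names = FALSE)
         else cd45_threshold
  low <- as.integer(names(med))[med < cut]
  if (length(low) == length(med))
    stop("no CD45-positive clusters: criterion removed every cluster")
  kept <- !(round1$labels %in% low)

  kept_table <- merged
  kept_table$values <- merged$values[kept, , drop = FALSE]
  if (!is.null(merged$provenance)) kept_table$provenance <- merged$provenance[kept]
  round2 <- phenograph(kept_table, k = k, channels = channels,
                       resolution = resolution, seed = derive_seed(seed, 2L))
  round2_labels <- rep(NA_integer_, n_events(merged))
  round2_labels[kept] <- round2$labels

  structure(list(round1_labels = round1$labels,
                 kept_mask = kept,
                 round2_labels = round2_labels,
                 round1_modularity = round1$modularity,
                 round2_modularity = round2$modularity,
                 removed_clusters = low,
                 parameters = list(k = k, seed = seed,
                                   cd45_channel = cd45_channel,
                                   cd45_mode = cd45_mode,
                                   cd45_threshold = cd45_threshold,
                                   resolution = resolution)),
            class = "pheno_result")
}

#' @export
print.pheno_result <- function(x, ...) {
  cat(sprintf(paste0("pheno_result: %d events; round 1: %d clusters ",
                     "(Q = %.3f); %d CD45-low cluster(s) removed (%d events); ",
                     "round 2: %d clusters (Q = %.3f)\n"),
              length(x$round1_labels), length(unique(x$round1_labels)),
              x$round1_modularity, length(x$removed_clusters),
              sum(!x$kept_mask),
              length(unique(x$round2_labels[x$kept_mask])),
              x$round2_modularity))
  invisible(x)
}

#' Bootstrap-Jaccard cluster stability
#'
#' For each bootstrap resample of events (with replacement) the unique
#' resampled events are re-clustered, and each original cluster scores the
#' maximum Jaccard coefficient between its membership and any new cluster,
#' both restricted to the resampled events.  The stability of a cluster is
#' the mean of these scores over replicates (clusterboot-style).  Replicates
#' in which a cluster has no resampled member are skipped for that cluster;
#' the number of contributing replicates is reported.
#'
#' @param events a transformed [event_table()] covering the labeled events.
#' @param labels integer cluster labels, one per event.
#' @param n_boot number of bootstrap replicates (>= 2; default 50).
#' @param k neighbour count used for re-clustering.
#' @param channels channels used for clustering.
#' @param resolution Louvain resolution.
#' @param seed integer seed.
#' @return data.frame with `cluster`, `stability` (mean bootstrap Jaccard in
#'   `[0, 1]`) and `n_replicates` (replicates that contributed).
#' @export
cluster_stability <- function(events, labels, n_boot = 50, k = 60,
                              channels = NULL, resolution = 1, seed = 0L) {
  stopifnot_event_table(events)
  n <- n_events(events)
  if (length(labels) != n) stop("labels must cover all events")
  if (n_boot < 2) stop("n_boot must be at least 2")
  clusters <- sort(unique(labels))
  scores <- matrix(NA_real_, length(clusters), n_boot,
                   dimnames = list(as.character(clusters), NULL))
  for (b in seq_len(n_boot)) {
    idx <- with_seed(derive_seed(seed, 100L + b), sample.int(n, n, replace = TRUE))
    uniq <- sort(unique(idx))
    bt <- events
    bt$values <- events$values[uniq, , drop = FALSE]
    part <- phenograph(bt, k = min(k, length(uniq) - 1L), channels = channels,
                       resolution = resolution, seed = derive_seed(seed, 200L + b))
    new_labels <- part$labels
    orig <- labels[uniq]
    for (ci in seq_along(clusters)) {
      in_orig <- orig == clusters[ci]
      n_orig <- sum(in_orig)
      if (n_orig == 0) next  # cluster absent from this resample: skip
      best <- 0
      for (nc in unique(new_labels)) {
        in_new <- new_labels == nc
        inter <- sum(in_orig & in_new)
        if (inter == 0) next
        best <- max(best, inter / (n_orig + sum(in_new) - inter))
      }
      scores[ci, b] <- best
    }
  }
  data.frame(cluster = clusters,
             stability = rowMeans(scores, na.rm = TRUE),
             n_replicates = rowSums(!is.na(scores)))
}

#' Clusters passing the bootstrap-stability criterion
#'
#' A cluster is accepted as stable when its mean bootstrap Jaccard
#' coefficient is strictly greater than the criterion (default 0.75, the
#' conventional cut-off for calling a cluster reproducible).
#'
#' @param stability a [cluster_stability()] table.
#' @param criterion stability threshold (default 0.75, strict `>`).
#' @return the cluster ids passing the criterion.
#' @export
stable_clusters <- function(stability, criterion = 0.75) {
  stability$cluster[stability$stability > criterion]
}

#' 2-D embedding of events via a pluggable backend
#'
#' Delegates to Rtsne (`method = "tsne"`) or uwot (`method = "umap"`); the
#' package makes no algorithmic claims about the embeddings beyond
#' coordinate export.
#'
#' @param events a transformed [event_table()].
#' @param method `"tsne"` or `"umap"`.
#' @param seed integer seed.
#' @param ... passed to the backend.
#' @return events x 2 coordinate matrix with `method` and `seed` attached as
#'   attributes.
#' @export
embed_coordinates <- function(events, method = c("tsne", "umap"), seed = 0L,
                              ...) {
  stopifnot_event_table(events)
  if (events$transform_state == "raw")
    stop("embed_coordinates expects a transformed table")
  method <- match.arg(method)
  m <- events$values
  coords <- if (method == "tsne") {
    if (!requireNamespace("Rtsne", quietly = TRUE))
      stop("embedding backend 'Rtsne' is not installed")
    perp <- min(30, max(1, floor((nrow(m) - 1) / 3)))
    with_seed(seed, Rtsne::Rtsne(m, perplexity = perp, check_duplicates = FALSE,
                                 ...)$Y)
  } else {
    if (!requireNamespace("uwot", quietly = TRUE))
      stop("embedding backend 'uwot' is not installed")
    nb <- min(15, nrow(m) - 1)
    with_seed(seed, uwot::umap(m, n_neighbors = nb, n_threads = 1, ...))
  }
  dimnames(coords) <- list(NULL, c("dim1", "dim2"))
  attr(coords, "method") <- method
  attr(coords, "seed") <- seed
  coords
}
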