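#' Single-cell quality-control filtering
#'
#' Filters are applied in order: (1) cells with fewer than `min_genes`
#' expressed genes are removed; (2) genes expressed in fewer than
#' `min_cells` cells are removed; (3) cells whose mitochondrial fraction is
#' not strictly under `max_mito` are removed (the fraction is computed on
#' the matrix as it stands after the gene filter).  A gene is "expressed"
#' in a cell when its value is > 0.  Mitochondrial genes are identified by
#' the `mito_prefix` (default `"MT-"`) or an explicit gene list.
#'
#' @param values genes x cells numeric matrix.
#' @param min_genes minimum expressed genes per cell (default 200; cells
#'   with >= 200 are kept).
#' @param min_cells minimum cells per gene (default 3; genes expressed in
#'   >= 3 cells are kept).
#' @param max_mito mitochondrial-fraction cap (default 0.05; cells with
#'   fraction < 0.05 are kept).
#' @param mito_prefix prefix identifying mitochondrial genes.
#' @param mito_genes explicit mitochondrial gene list (overrides the prefix).
#' @return list with `values` (filtered matrix) and `report` (stage-wise
#'   kept/removed counts and the thresholds used).
#' @export
sc_qc_filter <- function(values, min_genes = 200, min_cells = 3,
                         max_mito = 0.05, mito_prefix = "MT-",
                         mito_genes = NULL) {
  if (!is.matrix(values)) stop("values must be a genes x cells matrix")
  n_cells0 <- ncol(values)
  n_genes0 <- nrow(values)

  keep_cells <- colSums(values > 0) >= min_genes
  v <- values[, keep_cells, drop = FALSE]
  n_cells1 <- ncol(v)

  keep_genes <- rowSums(v > 0) >= min_cells
  v <- v[keep_genes, , drop = FALSE]
  n_genes1 <- nrow(v)

  mito <- if (is.null(mito_genes)) startsWith(rownames(v), mito_prefix)
          else rownames(v) %in% mito_genes
  mito_frac <- if (any(mito)) {
    tot <- colSums(v)
    ifelse(tot > 0, colSums(v[mito, , drop = FALSE]) / tot, 0)
  } else rep(0, ncol(v))
  keep_mito <- mito_frac < max_mito  # strictly under the cap
  v <- v[, keep_mito, drop = FALSE]

  report <- list(
    cells_in = n_cells0, genes_in = n_genes0,
    cells_after_gene_count = n_cells1,
    genes_after_cell_count = n_genes1,
    cells_after_mito = ncol(v),
    thresholds = list(min_genes = min_genes, min_cells = min_cells,
                      max_mito = max_mito))
  if (ncol(v) == 0 || nrow(v) == 0)
    stop("QC removed everything: ",
         paste(sprintf("%s=%d", names(report)[1:5], unlist(report[1:5])),
               collapse = ", "))
  list(values = v, report = report)
}

#' Per-cell-type average expression
#'
#' Arithmetic mean per gene and cell type on the matrix's working scale.
#'
#' @param values genes x cells matrix.
#' @param labels named (or positional) cell-type label per cell.
#' @return genes x cell-types average matrix.
#' @export
celltype_average <- function(values, labels) {
  if (length(labels) != ncol(values)) stop("every cell must be labeled")
  if (anyNA(labels)) stop("every cell must be labeled")
  types <- unique(labels)
  avg <- vapply(types, function(ty) {
    rowMeans(values[, labels == ty, drop = FALSE])
  }, numeric(nrow(values)))
  avg <- matrix(avg, nrow = nrow(values), ncol = length(types))
  dimnames(avg) <- list(rownames(values), types)
  avg
}

#' Overexpression calls (mean + 0.5 SD threshold)
#'
#' Per gene, the threshold is the across-cell-type mean plus half the
#' across-cell-type standard deviation (sample SD, n-1 denominator); a gene
#' is called overexpressed in a cell type when its average there strictly
#' exceeds the threshold.  With zero SD (all averages equal) no call is made.
#'
#' @param avg genes x cell-types average matrix (>= 2 cell types).
#' @param sd_factor multiplier on the SD (default 0.5).
#' @return an `overexpression_matrix`: binary genes x cell-types matrix with
#'   the per-gene thresholds in attribute `thresholds`.
#' @export
overexpression_calls <- function(avg, sd_factor = 0.5) {
  if (ncol(avg) < 2) stop("overexpression calls need at least 2 cell types")
  thr <- apply(avg, 1, function(x) mean(x) + sd_factor * sd(x))
  calls <- (avg > thr) * 1L
  structure(calls, class = c("overexpression_matrix", "matrix", "array"),
            thresholds = thr, sd_factor = sd_factor)
}

#' Binary subclustering of a gene cluster's overexpression patterns
#'
#' Agglomerative hierarchical clustering of genes on their binary
#' overexpression vectors (Euclidean distance on 0/1, complete linkage).
#' The tree is cut at `n_subclusters`; with `"auto"`, the cut maximizing the
#' mean silhouette width over 2..min(8, genes - 1) is chosen (ties to the
#' smaller count).  Identical call vectors across all genes yield a single
#' subcluster with a note.
#'
#' @param calls binary genes x cell-types matrix restricted to one gene
#'   cluster (>= 2 genes).
#' @param n_subclusters integer, or `"auto"`.
#' @return named integer vector of subcluster ids per gene, with attribute
#'   `note` when degenerate.
#' @export
binary_subcluster <- function(calls, n_subclusters = "auto") {
  if (nrow(calls) < 2) stop("subclustering needs at least 2 genes")
  m <- unclass(calls)
  if (all(apply(m, 2, function(col) length(unique(col)) == 1))) {
    out <- setNames(rep(1L, nrow(m)), rownames(m))
    attr(out, "note") <- "all overexpression patterns identical; single subcluster"
    return(out)
  }
  d <- dist(m, method = "euclidean")
  hc <- hclust(d, method = "complete")
  if (identical(n_subclusters, "auto")) {
    ks <- 2:min(8, nrow(m) - 1)
    sil <- vapply(ks, function(k) {
      cl <- cutree(hc, k)
      if (length(unique(cl)) < 2) return(-Inf)
      mean(cluster::silhouette(cl, d)[, "sil_width"])
    }, numeric(1))
    n_subclusters <- ks[which.max(sil)]
  }
  out <- cutree(hc, k = n_subclusters)
  setNames(as.integer(out), rownames(m))
}

#' Per-subcluster overexpressed-gene fractions (dotplot table)
#'
#' `fraction(subcluster, cell type)` = number of the subcluster's genes
#' called overexpressed in that cell type, divided by the subcluster size.
#'
#' @param assignments subcluster id per gene (from [binary_subcluster()]).
#' @param calls the matching [overexpression_calls()] matrix.
#' @return subclusters x cell-types fraction matrix.
#' @export
overexpression_fractions <- function(assignments, calls) {
  genes <- names(assignments)
  miss <- setdiff(genes, rownames(calls))
  if (length(miss)) stop("calls missing gene(s): ", paste(miss, collapse = ", "))
  subs <- sort(unique(assignments))
  out <- t(vapply(subs, function(s) {
    colMeans(unclass(calls)[genes[assignments == s], , drop = FALSE])
  }, numeric(ncol(calls))))
  dimnames(out) <- list(as.character(subs), colnames(calls))
  out
}

#' Full immune-gene-cluster overexpression analysis on single-cell data
#'
#' Chains QC filtering, per-cell-type averaging, overexpression calls,
#' per-cluster binary subclustering and fraction tables.
#'
#' @param values genes x cells matrix.
#' @param cell_labels cell-type label per cell.
#' @param ics named list of gene-id vectors.
#' @param ... passed to [sc_qc_filter()].
#' @return list with `qc_report`, `averages`, `calls`, and per-IC
#'   `subclusters` and `fractions`.
#' @export
sc_ic_analysis <- function(values, cell_labels, ics, ...) {
  qc <- sc_qc_filter(values, ...)
  labels <- cell_labels[colnames(qc$values)]
  avg <- celltype_average(qc$values, labels)
  calls <- overexpression_calls(avg)
  subclusters <- list()
  fractions <- list()
  for (ic in names(ics)) {
    genes <- intersect(ics[[ic]], rownames(calls))
    if (length(genes) < 2) next
    asg <- binary_subcluster(unclass(calls)[genes, , drop = FALSE])
    subclusters[[ic]] <- asg
    fractions[[ic]] <- overexpression_fractions(asg, calls)
  }
  list(qc_report = qc$report, averages = avg, calls = calls,
       subclusters = subclusters, fractions = fractions)
}

#' Differential-expression threshold filter
#'
#' Bonferroni-adjusts raw p-values (`p * n_tests`, capped at 1) and keeps
#' genes with log fold change strictly over `min_logfc` and adjusted p
#' strictly under `max_p`.
#'
#' @param stats data.frame with columns `gene`, `logfc`, `p`.
#' @param n_tests number of tests for the Bonferroni correction (must be at
#'   least the number of genes).
#' @param min_logfc log-fold-change threshold (default 0.25).
#' @param max_p adjusted-p threshold (default 0.05).
#' @return the retained subset of `stats` with an `p_adjusted` column.
#' @export
de_threshold_filter <- function(stats, n_tests, min_logfc = 0.25,
                                max_p = 0.05) {
  if (!all(c("gene", "logfc", "p") %in% names(stats)))
    stop("stats needs columns gene, logfc, p")
  if (any(stats$p < 0 | stats$p > 1)) stop("p-values must lie in [0, 1]")
  if (n_tests < nrow(stats))
    stop("n_tests (", n_tests, ") is smaller than the number of genes (",
         nrow(stats), ")")
  stats$p_adjusted <- pmin(stats$p * n_tests, 1)
  stats[stats$logfc > min_logfc & stats$p_adjusted < max_p, , drop = FALSE]
}

#' Rank-sum differential expression (pluggable stand-in)
#'
#' Per-gene two-sided Wilcoxon rank-sum test of one cell group against the
#' rest, with log2 fold change of group means (`log2(mean + 1)` difference).
#' A deliberately simple test feeding [de_threshold_filter()]; any per-gene
#' `(logfc, p)` table can be substituted.
#'
#' @param values genes x cells matrix.
#' @param group logical vector marking the cells of interest.
#' @return data.frame with `gene`, `logfc`, `p`.
#' @export
rank_sum_de <- function(values, group) {
  if (length(group) != ncol(values)) stop("group must cover all cells")
  if (!any(group) || all(group)) stop("both groups must be non-empty")
  a <- values[, group, drop = FALSE]
  b <- values[, !group, drop = FALSE]
  logfc <- log2(rowMeans(a) + 1) - log2(rowMeans(b) + 1)
  p <- vapply(seq_len(nrow(values)), function(i) {
    suppressWarnings(stats::wilcox.test(a[i, ], b[i, ], exact = FALSE)$p.value)
  }, numeric(1))
  p[is.na(p)] <- 1
  data.frame(gene = rownames(values), logfc = logfc, p = p,
             row.names = NULL)
}
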