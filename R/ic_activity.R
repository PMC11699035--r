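#' Read and write gene-cluster sets (GMT)
#'
#' GMT: one cluster per line, tab-separated `name`, `description`, genes.
#'
#' @param path GMT file.
#' @return named list of gene-id vectors.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop("malformed GMT line: ", substr(l, 1, 40))
    unique(f[-(1:2)])
  })
  names(out) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1))
  out
}

#' @rdname read_gmt
#' @param sets named list of gene vectors.
#' @param description optional per-set description.
#' @export
write_gmt <- function(sets, path, description = "synthetic") {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, description, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Variance filter
#'
#' Removes genes whose sample variance (n-1 denominator) is strictly below
#' `min_var`; intended for log2-normalized expression, the only scale on
#' which the default threshold is meaningful.
#'
#' @param m an [expression_matrix()] with >= 2 samples.
#' @param min_var variance threshold (default 0.05, strict `<` removal).
#' @return filtered `expression_matrix`.
#' @export
variance_filter <- function(m, min_var = 0.05) {
  if (!inherits(m, "expression_matrix")) m <- expression_matrix(as.matrix(m))
  if (ncol(m) < 2) stop("variance filter needs at least 2 samples")
  v <- apply(unclass(m), 1, var)
  keep <- v >= min_var  # strict < removal: exactly min_var is kept
  if (!any(keep)) stop("variance filter removed every gene")
  expression_matrix(unclass(m)[keep, , drop = FALSE], norm_state = norm_state(m),
                    gene_lengths = attr(m, "gene_lengths"))
}

#' Percentile-clipped 0-1 scaling
#'
#' Computes the `lo_pct` and `hi_pct` percentiles by linear interpolation
#' between order statistics, assigns values at or below the lower percentile
#' to 0 and at or above the upper percentile to 1, and rescales linearly in
#' between — the outlier-robust scaling used before gene-group medians.
#'
#' @param values numeric vector (one gene across samples).
#' @param lo_pct,hi_pct clipping percentiles (defaults 2 and 98).
#' @return vector in `[0, 1]`, or all-`NA` flagged with attribute
#'   `degenerate = TRUE` when the two percentiles coincide.
#' @export
clip_scale_01 <- function(values, lo_pct = 2, hi_pct = 98) {
  if (length(unique(values)) < 2 ||
      {
        p <- quantile(values, c(lo_pct, hi_pct) / 100, names = FALSE, type = 7)
        p[1] == p[2]
      }) {
    out <- rep(NA_real_, length(values))
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  pmin(1, pmax(0, (values - p[1]) / (p[2] - p[1])))
}

#' Largest positively intercorrelated gene group
#'
#' The maximum-cardinality gene subset in which every pair has strictly
#' positive Pearson correlation — a maximum clique in the
#' positive-correlation graph.  Exact branch-and-bound search is used up to
#' `exact_limit` genes; above it, a greedy peel iteratively drops the gene
#' with the most nonpositive correlations until all remaining pairs are
#' positive.  Ties resolve to the group found first in lexicographic gene
#' order.  If no pair correlates positively, the single gene with the
#' highest mean correlation to the others is returned.
#'
#' @param scaled genes x samples matrix of scaled values (rows are genes).
#' @param exact_limit maximum gene count for the exact search (default 40).
#' @return character vector of gene ids, with attribute
#'   `method = "exact"`/`"greedy"`.
#' @export
largest_positive_corr_group <- function(scaled, exact_limit = 40) {
  genes <- rownames(scaled)
  if (is.null(genes)) stop("scaled matrix must have gene row names")
  ord <- order(genes)
  scaled <- scaled[ord, , drop = FALSE]
  genes <- genes[ord]
  n <- length(genes)
  if (n == 1) return(structure(genes, method = "exact"))
  r <- suppressWarnings(cor(t(scaled)))
  pos <- r > 0
  diag(pos) <- TRUE
  pos[is.na(pos)] <- FALSE
  if (!any(pos[upper.tri(pos)])) {
    mean_r <- rowMeans(r, na.rm = TRUE)
    return(structure(genes[which.max(mean_r)], method = "fallback"))
  }
  if (n <= exact_limit) {
    sel <- max_clique_exact(pos)
    structure(genes[sel], method = "exact")
  } else {
    keep <- seq_len(n)
    repeat {
      bad <- colSums(!pos[keep, keep, drop = FALSE])
      if (all(bad == 0)) break
      # drop the gene with most nonpositive pairs; ties drop the later gene
      drop_i <- which(bad == max(bad))
      keep <- keep[-drop_i[length(drop_i)]]
    }
    structure(genes[keep], method = "greedy")
  }
}

# Exact maximum clique by depth-first branch and bound over vertices in
# index order; only strict improvements replace the incumbent, so the first
# (lexicographically earliest) maximum clique is kept.
max_clique_exact <- function(adj) {
  n <- nrow(adj)
  best <- integer(0)
  search <- function(current, candidates) {
    if (length(current) > length(best)) best <<- current
    if (!length(candidates)) return(invisible(NULL))
    for (i in seq_along(candidates)) {
      v <- candidates[i]
      rest <- candidates[-seq_len(i)]
      if (length(current) + 1 + length(rest) <= length(best)) break  # bound
      search(c(current, v), rest[adj[v, rest]])
    }
    invisible(NULL)
  }
  search(integer(0), seq_len(n))
  best
}

#' Immune-gene-cluster activity scores
#'
#' Per cluster: restrict to genes present in the matrix, drop low-variance
#' genes (see [variance_filter()]), scale every gene to `[0, 1]` with 2nd/98th
#' percentile clipping, find the largest positively intercorrelated gene
#' group, and report each sample's activity as the median of the group's
#' scaled values.  Activities are therefore in `[0, 1]` by construction.
#'
#' @param bulk a normalized (log2-scale) [expression_matrix()].
#' @param ics named list of gene-id vectors (see [read_gmt()]).
#' @param min_var variance threshold (default 0.05).
#' @return an `activity_matrix`: ICs x samples matrix; clusters with no
#'   surviving genes get `NA` rows and are flagged in the `undefined`
#'   attribute; the selected gene group per IC is in attribute `groups`.
#' @export
ic_activity <- function(bulk, ics, min_var = 0.05) {
  if (!inherits(bulk, "expression_matrix")) bulk <- expression_matrix(as.matrix(bulk))
  act <- matrix(NA_real_, length(ics), ncol(bulk),
                dimnames = list(names(ics), colnames(bulk)))
  groups <- setNames(vector("list", length(ics)), names(ics))
  undefined <- character()
  vals <- unclass(bulk)
  gene_var <- apply(vals, 1, var)
  for (ic in names(ics)) {
    genes <- intersect(ics[[ic]], rownames(vals))
    genes <- genes[gene_var[genes] >= min_var]
    if (!length(genes)) {
      undefined <- c(undefined, ic)
      next
    }
    scaled <- t(vapply(genes, function(g) clip_scale_01(vals[g, ]),
                       numeric(ncol(vals))))
    rownames(scaled) <- genes
    ok <- !apply(scaled, 1, anyNA)  # degenerate scalings are excluded
    if (!any(ok)) {
      undefined <- c(undefined, ic)
      next
    }
    scaled <- scaled[ok, , drop = FALSE]
    grp <- largest_positive_corr_group(scaled)
    groups[[ic]] <- grp
    act[ic, ] <- apply(scaled[grp, , drop = FALSE], 2, median)
  }
  structure(act, class = c("activity_matrix", "matrix", "array"),
            groups = groups, undefined = undefined)
}
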