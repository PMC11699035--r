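#' Default marker-rule table for phenotype annotation
#'
#' A user-editable rule table standing in for expert annotation.  Rules are
#' checked in order; the first rule whose `hi` markers are all "hi" and
#' whose `lo` markers are all "lo" provides the annotation.  Clusters
#' matching no rule are annotated `"unassigned"`.
#'
#' @return list of rules, each `list(annotation =, hi =, lo =)`.
#' @export
default_marker_rules <- function() {
  list(
    list(annotation = "CD19+ myeloid", hi = c("CD19", "CD14"), lo = "CD3"),
    list(annotation = "CD3+ myeloid", hi = c("CD3", "CD14"), lo = character()),
    list(annotation = "Neutrophil", hi = c("CD66b"), lo = c("CD3", "CD19")),
    list(annotation = "MDM", hi = c("CD14", "CD45"), lo = c("CD3", "CD19", "CD66b")),
    list(annotation = "MG", hi = "CD14", lo = c("CD3", "CD19", "CD66b", "CD45")),
    list(annotation = "CD4 T cell", hi = c("CD3", "CD4"), lo = c("CD14", "CD8")),
    list(annotation = "CD8 T cell", hi = c("CD3", "CD8"), lo = c("CD14", "CD4")),
    list(annotation = "DNT", hi = "CD3", lo = c("CD4", "CD8", "CD14")),
    list(annotation = "T cell", hi = "CD3", lo = "CD14"),
    list(annotation = "B cell", hi = "CD19", lo = c("CD14", "CD3"))
  )
}

#' Per-cluster marker summaries with lo/mid/hi levels
#'
#' Computes per-cluster per-channel median intensities and discretizes them
#' to three levels by tertiles of the per-cluster medians within each
#' channel (a scale-free rule: the lowest third of cluster medians is "lo",
#' the middle third "mid", the top third "hi").  A marker-rule table then
#' proposes a phenotype annotation per cluster.
#'
#' @param events a transformed [event_table()].
#' @param labels integer cluster labels per event.
#' @param rules marker-rule table (see [default_marker_rules()]).
#' @return list of `marker_summary` objects (cluster id, medians, levels,
#'   annotation), one per cluster.
#' @export
summarize_markers <- function(events, labels, rules = default_marker_rules()) {
  stopifnot_event_table(events)
  if (length(labels) != n_events(events)) stop("labels must cover all events")
  clusters <- sort(unique(labels))
  med <- t(vapply(clusters, function(cl) {
    apply(events$values[labels == cl, , drop = FALSE], 2, median)
  }, numeric(length(events$channels))))
  dimnames(med) <- list(as.character(clusters), events$channels)

  levels <- med
  mode(levels) <- "character"
  for (ch in events$channels) {
    cuts <- quantile(med[, ch], c(1 / 3, 2 / 3), names = FALSE)
    levels[, ch] <- ifelse(med[, ch] <= cuts[1], "lo",
                           ifelse(med[, ch] <= cuts[2], "mid", "hi"))
  }

  lapply(seq_along(clusters), function(i) {
    lv <- levels[i, ]
    ann <- "unassigned"
    for (r in rules) {
      known <- all(c(r$hi, r$lo) %in% events$channels)
      if (known && all(lv[r$hi] == "hi") && all(lv[r$lo] == "lo")) {
        ann <- r$annotation
        break
      }
    }
    structure(list(cluster = clusters[i], medians = med[i, ],
                   levels = lv, annotation = ann),
              class = "marker_summary")
  })
}

#' @export
print.marker_summary <- function(x, ...) {
  hi <- names(x$levels)[x$levels == "hi"]
  cat(sprintf("cluster %s: %s  [hi: %s]\n", x$cluster, x$annotation,
              paste(hi, collapse = ", ")))
  invisible(x)
}

#' Sample-by-cluster composition matrix
#'
#' Fraction of each sample's events falling in each cluster.  With
#' `denominator = "cd45_kept"` fractions are taken over the labeled
#' (CD45-kept) events and each row sums to 1; with `"all_events"` fractions
#' are taken over all of a sample's events including those removed upstream
#' (supply `total_events`), so rows may sum to less than 1.
#'
#' @param labels cluster labels of the labeled events.
#' @param provenance sample id per labeled event.
#' @param denominator `"cd45_kept"` or `"all_events"`.
#' @param total_events named vector of per-sample total event counts
#'   (required for `"all_events"`).
#' @return a `composition_matrix`: samples x clusters fraction matrix.
#'   Samples with a zero denominator get `NA` rows and are listed in the
#'   `undefined_samples` attribute rather than silently zeroed.
#' @export
composition <- function(labels, provenance,
                        denominator = c("cd45_kept", "all_events"),
                        total_events = NULL) {
  denominator <- match.arg(denominator)
  if (length(labels) != length(provenance))
    stop("provenance must cover all labeled events")
  counts <- table(factor(provenance), factor(labels))
  denom <- if (denominator == "cd45_kept") {
    rowSums(counts)
  } else {
    if (is.null(total_events))
      stop("total_events is required for denominator = 'all_events'")
    miss <- setdiff(rownames(counts), names(total_events))
    if (length(miss)) stop("total_events missing sample(s): ",
                           paste(miss, collapse = ", "))
    total_events[rownames(counts)]
  }
  frac <- sweep(unclass(counts), 1, denom, "/")
  undefined <- rownames(frac)[denom == 0]
  frac[denom == 0, ] <- NA_real_
  structure(frac, class = c("composition_matrix", "matrix"),
            denominator = denominator, undefined_samples = undefined)
}

#' Group phenoclusters into cell-type categories
#'
#' Relabels a cluster partition by a total cluster-to-cell-type mapping.
#' Composition over cell types equals the row-wise sums of the cluster
#' composition, so row sums are preserved exactly.
#'
#' @param labels cluster labels.
#' @param mapping named vector: names are cluster ids (as character), values
#'   are cell-type names.  Must cover every cluster present.
#' @return character vector of cell-type labels per event.
#' @export
group_to_celltypes <- function(labels, mapping) {
  present <- as.character(sort(unique(labels)))
  miss <- setdiff(present, names(mapping))
  if (length(miss))
    stop("no cell-type mapping for cluster(s): ", paste(miss, collapse = ", "))
  unname(mapping[as.character(labels)])
}

#' Pairwise correlation report with two-sided p-values
#'
#' Correlates the columns (clusters/cell types, `axis = "celltypes"`) or the
#' rows (samples, `axis = "samples"`) of a composition matrix.  Two-sided
#' p-values come from `t = r * sqrt(n - 2) / sqrt(1 - r^2)` on `n - 2`
#' degrees of freedom; Spearman uses the same t approximation on rank
#' correlations.  Zero-variance vectors yield `NA` correlations and are
#' flagged.
#'
#' @param m a [composition()] matrix (samples x clusters), or any numeric
#'   matrix laid out the same way.
#' @param axis `"celltypes"` (correlate columns across samples) or
#'   `"samples"` (correlate rows across clusters).
#' @param method `"pearson"` or `"spearman"`.
#' @return a `correlation_report`: `r` and `p` matrices, `n` observations per
#'   pair, the method, formatted p-values and flagged degenerate variables.
#' @export
correlate <- function(m, axis = c("celltypes", "samples"),
                      method = c("pearson", "spearman")) {
  axis <- match.arg(axis)
  method <- match.arg(method)
  x <- if (axis == "samples") t(unclass(m)) else unclass(m)
  x <- x[stats::complete.cases(x), , drop = FALSE]
  n <- nrow(x)
  if (n < 3) stop("at least 3 observations per pair are required")
  degenerate <- colnames(x)[apply(x, 2, function(v) var(v) == 0)]
  suppressWarnings(r <- cor(x, method = method))
  diag(r) <- 1
  p <- correlation_pvalue(r, n)
  structure(list(method = method, r = r, p = p, n = n,
                 p_formatted = matrix(format_pvalue(p), nrow(p),
                                      dimnames = dimnames(p)),
                 degenerate = degenerate),
            class = "correlation_report")
}

#' Two-sided correlation p-value from the t distribution
#'
#' @param r correlation (scalar or matrix), `|r| <= 1`.
#' @param n number of paired observations.
#' @return two-sided p-values; `|r| = 1` maps to the double-precision floor.
#' @export
correlation_pvalue <- function(r, n) {
  tstat <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, 0))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  p[abs(r) >= 1] <- 0
  p
}

#' @export
print.correlation_report <- function(x, ...) {
  cat(sprintf("correlation_report (%s, n = %d):\n", x$method, x$n))
  print(round(x$r, 3))
  if (length(x$degenerate))
    cat("zero-variance (NA) variables:", paste(x$degenerate, collapse = ", "), "\n")
  invisible(x)
}
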