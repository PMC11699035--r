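#' Construct an expression matrix
#'
#' A genes x samples numeric matrix with an ordered record of the
#' normalizations applied (`tpm`, `quantile`, `log2`, in that order) and
#' optional per-gene lengths needed for TPM.
#'
#' @param values numeric matrix with gene row names and sample column names.
#' @param norm_state character vector, subset of
#'   `c("tpm", "quantile", "log2")` in application order.
#' @param gene_lengths optional named per-gene lengths in bases.
#' @return an `expression_matrix` (a classed matrix).
#' @export
expression_matrix <- function(values, norm_state = character(),
                              gene_lengths = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("values must be a numeric matrix")
  if (is.null(rownames(values))) stop("values must have gene row names")
  if (anyDuplicated(rownames(values))) stop("gene identifiers must be unique")
  allowed <- c("tpm", "quantile", "log2")
  if (!all(norm_state %in% allowed))
    stop("unknown normalization flag(s): ",
         paste(setdiff(norm_state, allowed), collapse = ", "))
  if (!identical(norm_state, allowed[allowed %in% norm_state]))
    stop("normalization flags must be ordered tpm -> quantile -> log2")
  if (!"log2" %in% norm_state && any(values < 0))
    stop("negative values are not allowed before log2 transformation")
  structure(values, class = c("expression_matrix", "matrix", "array"),
            norm_state = norm_state, gene_lengths = gene_lengths)
}

norm_state <- function(m) attr(m, "norm_state") %||% character()

#' TPM normalization
#'
#' Per sample: `rate_g = count_g / length_kb_g`;
#' `TPM_g = rate_g / sum(rate) * 1e6`.  Columns sum to one million.
#'
#' @param counts raw-count [expression_matrix()] with `gene_lengths`, or a
#'   plain matrix plus `gene_lengths`.
#' @param gene_lengths named per-gene lengths in bases (overrides the
#'   attribute).
#' @return TPM-normalized `expression_matrix`.
#' @export
tpm_normalize <- function(counts, gene_lengths = NULL) {
  if (!inherits(counts, "expression_matrix"))
    counts <- expression_matrix(as.matrix(counts), gene_lengths = gene_lengths)
  if (length(norm_state(counts)))
    stop("tpm_normalize expects raw counts")
  len <- gene_lengths %||% attr(counts, "gene_lengths")
  if (is.null(len)) stop("gene lengths are required for TPM")
  miss <- setdiff(rownames(counts), names(len))
  if (length(miss)) stop("missing gene length for: ", paste(miss, collapse = ", "))
  len <- len[rownames(counts)]
  if (any(len <= 0)) stop("gene lengths must be positive")
  rate <- unclass(counts) / (len / 1000)
  libsize <- colSums(rate)
  zero <- colnames(counts)[libsize == 0]
  if (length(zero)) stop("zero library: sample(s) ", paste(zero, collapse = ", "))
  expression_matrix(sweep(rate, 2, libsize, "/") * 1e6,
                    norm_state = "tpm", gene_lengths = len)
}

#' Quantile normalization
#'
#' Each sample's sorted values are replaced by the cross-sample mean of
#' sorted values, mapped back by rank; tied values receive the mean over
#' their tied rank range.  Delegates to `limma::normalizeQuantiles`
#' (`ties = TRUE`), the standard implementation of exactly this convention.
#'
#' @param m an [expression_matrix()] (>= 2 samples).
#' @return quantile-normalized `expression_matrix`.
#' @export
quantile_normalize <- function(m) {
  if (!inherits(m, "expression_matrix")) m <- expression_matrix(as.matrix(m))
  if (ncol(m) < 2) stop("quantile normalization needs at least 2 samples")
  if ("quantile" %in% norm_state(m) || "log2" %in% norm_state(m))
    stop("quantile normalization must precede log2 and is applied once")
  q <- limma::normalizeQuantiles(unclass(m), ties = TRUE)
  dimnames(q) <- dimnames(m)
  expression_matrix(q, norm_state = c(norm_state(m), "quantile"),
                    gene_lengths = attr(m, "gene_lengths"))
}

#' Log2 transformation
#'
#' `x -> log2(x + 1)`, the final normalization step before analysis.
#'
#' @param m an [expression_matrix()].
#' @return log2-scale `expression_matrix`.
#' @export
log2_transform <- function(m) {
  if (!inherits(m, "expression_matrix")) m <- expression_matrix(as.matrix(m))
  if ("log2" %in% norm_state(m)) stop("matrix is already log2-transformed")
  expression_matrix(log2(unclass(m) + 1),
                    norm_state = c(norm_state(m), "log2"),
                    gene_lengths = attr(m, "gene_lengths"))
}

#' Build a median reference panel from purified profiles
#'
#' Per gene and cell type, the median across that type's purified samples
#' (mean-of-middle convention for even counts, i.e. `stats::median`).
#'
#' @param purified normalized [expression_matrix()] of purified samples.
#' @param type_labels named vector mapping every sample to its cell type.
#' @param restriction optional gene set restricting downstream regressions
#'   (e.g. immune-related gene-cluster genes); defaults to all panel genes.
#' @return a `reference_panel`: genes x cell-types median matrix, per-type
#'   sample counts, the restriction set and the normalization state.
#' @export
build_reference <- function(purified, type_labels, restriction = NULL) {
  if (!inherits(purified, "expression_matrix"))
    purified <- expression_matrix(as.matrix(purified))
  miss <- setdiff(colnames(purified), names(type_labels))
  if (length(miss)) stop("unlabeled sample(s): ", paste(miss, collapse = ", "))
  type_labels <- type_labels[colnames(purified)]
  types <- unique(type_labels)
  counts <- table(factor(type_labels, levels = types))
  if (any(counts == 0)) stop("cell type with zero samples")
  med <- vapply(types, function(ty) {
    apply(unclass(purified)[, type_labels == ty, drop = FALSE], 1, median)
  }, numeric(nrow(purified)))
  med <- matrix(med, nrow = nrow(purified), ncol = length(types))
  dimnames(med) <- list(rownames(purified), types)
  if (is.null(restriction)) restriction <- rownames(purified)
  bad <- setdiff(restriction, rownames(purified))
  structure(list(medians = med,
                 sample_counts = as.integer(counts),
                 cell_types = types,
                 restriction = setdiff(restriction, bad),
                 norm_state = norm_state(purified)),
            class = "reference_panel")
}

#' Elastic-net deconvolution of bulk samples
#'
#' Estimates per-sample cell-type coefficients by regressing each bulk
#' sample's expression over the restriction genes on the reference-panel
#' columns, with elastic-net regularization (`glmnet`, mixing parameter
#' `alpha`) and the penalty weight chosen per sample by seeded k-fold
#' cross-validation over genes (folds stratified by expression decile).
#' Because mixing of cell populations is linear in transcript abundance, the
#' regression is performed on the linear scale; log2-stored inputs are
#' un-logged internally (`2^x - 1`).  Coefficients are reported raw
#' (negative values included); see [as_proportions()] for the clipped,
#' renormalized view.
#'
#' @param bulk normalized [expression_matrix()] of bulk samples (same
#'   normalization as the panel).
#' @param panel a [build_reference()] panel.
#' @param alpha elastic-net mixing parameter (default 0.25).
#' @param folds cross-validation folds (default 10).
#' @param lambda `"cv"` (default) or a fixed numeric penalty; use a small
#'   value to approach the ordinary-least-squares limit.
#' @param intercept include an intercept (default `TRUE`).
#' @param seed integer seed for fold assignment.
#' @return a `deconv_result`: samples x cell-types coefficient matrix,
#'   chosen `lambda` and intercept per sample, `alpha`, fold count and the
#'   genes used.
#' @export
deconvolve <- function(bulk, panel, alpha = 0.25, folds = 10, lambda = "cv",
                       intercept = TRUE, seed = 0L) {
  if (!inherits(panel, "reference_panel")) stop("panel must be a reference_panel")
  if (!inherits(bulk, "expression_matrix")) bulk <- expression_matrix(as.matrix(bulk))
  if (!identical(norm_state(bulk), panel$norm_state))
    stop("bulk and panel must share the same normalization state")
  genes <- intersect(panel$restriction, rownames(bulk))
  if (!length(genes)) stop("restriction gene set does not intersect bulk genes")
  if (length(genes) < folds)
    stop("fewer restriction genes (", length(genes), ") than folds (", folds, ")")

  unlog <- "log2" %in% norm_state(bulk)
  X <- panel$medians[genes, , drop = FALSE]
  Y <- unclass(bulk)[genes, , drop = FALSE]
  if (unlog) {
    X <- 2^X - 1
    Y <- 2^Y - 1
  }
  n_types <- ncol(X)
  coef_mat <- matrix(NA_real_, ncol(Y), n_types,
                     dimnames = list(colnames(Y), colnames(X)))
  lambdas <- numeric(ncol(Y))
  intercepts <- numeric(ncol(Y))
  for (j in seq_len(ncol(Y))) {
    y <- Y[, j]
    if (identical(lambda, "cv")) {
      foldid <- stratified_folds(y, folds, derive_seed(seed, j))
      cv <- glmnet::cv.glmnet(X, y, alpha = alpha, foldid = foldid,
                              intercept = intercept, standardize = TRUE)
      lam <- cv$lambda.min
      fit <- cv$glmnet.fit
    } else {
      lam <- as.numeric(lambda)
      fit <- glmnet::glmnet(X, y, alpha = alpha, lambda = c(lam * 100, lam),
                            intercept = intercept, standardize = TRUE,
                            thresh = 1e-12)
    }
    cf <- as.numeric(glmnet::coef.glmnet(fit, s = lam, exact = FALSE))
    intercepts[j] <- cf[1]
    coef_mat[j, ] <- cf[-1]
    lambdas[j] <- lam
  }
  structure(list(coefficients = coef_mat, alpha = alpha, folds = folds,
                 lambda = lambdas, intercept = intercepts,
                 genes = genes, seed = seed),
            class = "deconv_result")
}

# Seeded fold assignment stratified by expression decile: genes are binned
# into deciles of y and folds filled cyclically within each bin after a
# seeded shuffle, so folds are balanced across the expression range.
stratified_folds <- function(y, folds, seed) {
  dec <- cut(rank(y, ties.method = "first"), breaks = 10, labels = FALSE)
  foldid <- integer(length(y))
  with_seed(seed, {
    for (d in unique(dec)) {
      idx <- which(dec == d)
      idx <- idx[sample.int(length(idx))]
      foldid[idx] <- rep_len(sample.int(folds), length(idx))
    }
  })
  foldid
}

#' Clipped, renormalized proportions from deconvolution coefficients
#'
#' A derived view: negative coefficients are clipped to zero and each
#' sample's remaining coefficients renormalized to sum to 1.
#'
#' @param res a [deconvolve()] result.
#' @return samples x cell-types proportion matrix.
#' @export
as_proportions <- function(res) {
  stopifnot(inherits(res, "deconv_result"))
  cf <- pmax(res$coefficients, 0)
  s <- rowSums(cf)
  s[s == 0] <- NA_real_
  cf / s
}

#' @export
print.deconv_result <- function(x, ...) {
  cat(sprintf("deconv_result: %d samples x %d cell types (alpha = %g, %d-fold CV)\n",
              nrow(x$coefficients), ncol(x$coefficients), x$alpha, x$folds))
  print(round(head(x$coefficients), 3))
  invisible(x)
}
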