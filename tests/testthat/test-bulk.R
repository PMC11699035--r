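test_that("TPM follows the per-kilobase rate formula and sums to 1e6", {
  counts <- matrix(c(10, 90), 2, 1, dimnames = list(c("g1", "g2"), "s1"))
  tpm <- tpm_normalize(counts, gene_lengths = c(g1 = 1000, g2 = 1000))
  expect_equal(unclass(tpm)[, 1], c(g1 = 1e5, g2 = 9e5))
  counts2 <- matrix(c(10, 10), 2, 1, dimnames = list(c("g1", "g2"), "s1"))
  tpm2 <- tpm_normalize(counts2, gene_lengths = c(g1 = 1000, g2 = 2000))
  expect_equal(unclass(tpm2)[, 1], c(g1 = 2e6 / 3, g2 = 1e6 / 3),
               tolerance = 1e-9)
  expect_equal(unname(colSums(unclass(tpm2))), 1e6)
  # degenerate inputs
  zero <- matrix(c(0, 0), 2, 1, dimnames = list(c("g1", "g2"), "s1"))
  expect_error(tpm_normalize(zero, c(g1 = 1000, g2 = 1000)), "zero library")
  expect_error(tpm_normalize(counts, c(g1 = 1000)), "missing gene length.*g2")
})

test_that("quantile normalization equalizes sorted vectors and is idempotent", {
  m <- matrix(c(1, 2, 3, 4, 5, 6), 3, 2,
              dimnames = list(paste0("g", 1:3), c("s1", "s2")))
  q <- quantile_normalize(m)
  expect_equal(unname(unclass(q)[, 1]), c(2.5, 3.5, 4.5))
  expect_equal(unname(unclass(q)[, 2]), c(2.5, 3.5, 4.5))
  # identical samples are a fixed point
  ident <- matrix(c(5, 1, 3, 5, 1, 3), 3, 2,
                  dimnames = list(paste0("g", 1:3), c("a", "b")))
  expect_equal(unclass(quantile_normalize(ident)), unclass(ident),
               ignore_attr = TRUE)
  # after normalization all sorted sample vectors agree; reapplying to the
  # same values changes nothing
  set.seed(12)
  big <- matrix(rexp(500), 100, 5,
                dimnames = list(sprintf("g%03d", 1:100), paste0("s", 1:5)))
  q1 <- unclass(quantile_normalize(big))
  sorted <- apply(q1, 2, sort)
  expect_lt(max(abs(sorted - sorted[, 1])), 1e-12)
  q2 <- limma::normalizeQuantiles(q1, ties = TRUE)
  expect_equal(unname(q2), unname(q1), tolerance = 1e-12)
})

test_that("reference medians use the mean-of-middle convention", {
  m <- log2_expr(matrix(c(1, 2, 9,
                          1, 3, 5), 2, 3, byrow = TRUE,
                        dimnames = list(c("g1", "g2"), c("a1", "a2", "a3"))))
  panel <- build_reference(m, c(a1 = "A", a2 = "A", a3 = "A"))
  expect_equal(unname(panel$medians[, "A"]), c(2, 3))
  even <- log2_expr(matrix(c(1, 3), 1, 2,
                           dimnames = list("g1", c("a1", "a2"))))
  panel2 <- build_reference(even, c(a1 = "A", a2 = "A"))
  expect_equal(unname(panel2$medians["g1", "A"]), 2)
  # single sample per type: reference equals the sample
  single <- log2_expr(matrix(c(4, 7), 2, 1,
                             dimnames = list(c("g1", "g2"), "a1")))
  panel3 <- build_reference(single, c(a1 = "A"))
  expect_equal(unname(panel3$medians[, "A"]), c(4, 7))
  expect_error(build_reference(single, c(zz = "A")), "unlabeled")
})

ols_design <- function(n_genes = 200, seed = 3L) {
  profiles <- synthetic_reference_profiles(n_genes = n_genes,
                                           markers_per_type = 30, seed = seed)
  panel <- build_reference(log2_expr(log2(profiles + 1)),
                           setNames(colnames(profiles), colnames(profiles)))
  list(profiles = profiles, panel = panel)
}

test_that("a pure reference column deconvolves to the unit coefficient", {
  d <- ols_design()
  W <- matrix(0, 1, 6, dimnames = list("s1", colnames(d$profiles)))
  W[1, "MG"] <- 1
  bulk <- generate_bulk_mixtures(bulk_config(d$profiles, W, noise_sd = 0))
  res <- deconvolve(bulk, d$panel, lambda = 1e-4)
  expect_lt(abs(res$coefficients["s1", "MG"] - 1), 0.01)
  expect_lt(max(abs(res$coefficients["s1", colnames(W) != "MG"])), 0.01)
})

test_that("noiseless mixtures reproduce their weights at the OLS limit", {
  d <- ols_design()
  W <- matrix(0, 1, 6, dimnames = list("s1", colnames(d$profiles)))
  W[1, c("MG", "CD4T")] <- c(0.3, 0.7)
  bulk <- generate_bulk_mixtures(bulk_config(d$profiles, W, noise_sd = 0))
  res <- deconvolve(bulk, d$panel, lambda = 1e-4)
  expect_equal(unname(res$coefficients["s1", c("MG", "CD4T")]), c(0.3, 0.7),
               tolerance = 0.01)
  # independent OLS oracle on the same linear-scale design
  X <- 2^d$panel$medians - 1
  y <- 2^unclass(bulk)[, 1] - 1
  ols <- coef(lm(y ~ X))[-1]
  expect_equal(unname(res$coefficients["s1", ]), unname(ols), tolerance = 0.01)
})

test_that("coefficients shrink monotonically in lambda on an orthogonal design", {
  X <- log2_expr(matrix(0, 40, 1, dimnames = list(sprintf("g%02d", 1:40), "s1")))
  prof <- matrix(0, 40, 2, dimnames = list(sprintf("g%02d", 1:40), c("A", "B")))
  prof[1:20, "A"] <- 2^seq(2, 6, length.out = 20) - 1
  prof[21:40, "B"] <- 2^seq(2, 6, length.out = 20) - 1
  panel <- build_reference(log2_expr(log2(prof + 1)),
                           c(A = "A", B = "B"))
  W <- matrix(c(0.5, 0.5), 1, 2, dimnames = list("s1", c("A", "B")))
  bulk <- generate_bulk_mixtures(bulk_config(prof, W, noise_sd = 0))
  lams <- c(1e-3, 1, 10, 100)
  mags <- vapply(lams, function(l) {
    sum(abs(deconvolve(bulk, panel, lambda = l)$coefficients))
  }, numeric(1))
  expect_true(all(diff(mags) <= 1e-8))
})

test_that("coefficients respond continuously to small lambda perturbations", {
  d <- ols_design()
  W <- random_mixing_weights(1, seed = 31L)
  bulk <- generate_bulk_mixtures(bulk_config(d$profiles, W, noise_sd = 0.05,
                                             seed = 32L))
  base <- deconvolve(bulk, d$panel, lambda = 2)$coefficients
  bumped <- deconvolve(bulk, d$panel, lambda = 2 * 1.01)$coefficients
  # change relative to the coefficient scale (near-zero entries wander at
  # the solver tolerance and carry no per-entry relative meaning)
  expect_lt(max(abs(bumped - base)) / max(abs(base)), 0.05)
})

test_that("deconvolution is deterministic under a fixed CV seed", {
  d <- ols_design()
  W <- random_mixing_weights(3, seed = 5L)
  bulk <- generate_bulk_mixtures(bulk_config(d$profiles, W, noise_sd = 0.1,
                                             seed = 8L))
  r1 <- deconvolve(bulk, d$panel, seed = 17L)
  r2 <- deconvolve(bulk, d$panel, seed = 17L)
  expect_identical(r1$coefficients, r2$coefficients)
  expect_identical(r1$lambda, r2$lambda)
})

test_that("deconvolution validates gene overlap and normalization state", {
  d <- ols_design()
  W <- random_mixing_weights(2, seed = 5L)
  bulk <- generate_bulk_mixtures(bulk_config(d$profiles, W, noise_sd = 0))
  other <- expression_matrix(matrix(1:4, 2, 2,
                                    dimnames = list(c("zz1", "zz2"),
                                                    c("s1", "s2"))),
                             norm_state = c("tpm", "quantile", "log2"))
  expect_error(deconvolve(other, d$panel), "does not intersect")
  raw <- expression_matrix(2^unclass(bulk) - 1)
  expect_error(deconvolve(raw, d$panel), "normalization state")
})

test_that("the proportion view clips negatives and renormalizes", {
  res <- structure(list(coefficients = matrix(c(0.5, -0.1, 0.7), 1,
                                              dimnames = list("s1",
                                                              c("A", "B", "C")))),
                   class = "deconv_result")
  pr <- as_proportions(res)
  expect_equal(unname(pr["s1", ]), c(0.5, 0, 0.7) / 1.2)
  expect_equal(sum(pr), 1)
})
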