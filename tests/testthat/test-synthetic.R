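test_that("single-population cohort is degenerate and fully labeled", {
  pops <- list(population_spec("only", c(CD45 = 3), fraction = 1))
  cfg <- cohort_config(list(list(sample_id = "s1", n_events = 100)),
                       panel = c("CD45"), doublet_rate = 0, seed = 1L)
  cohort <- generate_event_cohort(cfg, pops)
  expect_length(cohort, 1)
  expect_equal(nrow(cohort$s1$values), 100)
  expect_true(all(cohort$s1$truth$labels == "only"))
})

test_that("population label counts respect binomial sampling bounds", {
  pops <- list(
    population_spec("a", c(CD45 = 4), fraction = 0.7),
    population_spec("b", c(CD45 = 2), fraction = 0.2),
    population_spec("c", c(CD45 = 0.5), fraction = 0.1))
  cfg <- cohort_config(list(list(sample_id = "s1", n_events = 10000)),
                       panel = "CD45", doublet_rate = 0, seed = 11L)
  labels <- generate_event_cohort(cfg, pops)$s1$truth$labels
  n <- 10000
  for (i in seq_along(pops)) {
    p <- pops[[i]]$fraction
    expect_lt(abs(sum(labels == pops[[i]]$name) - n * p),
              3 * sqrt(n * p * (1 - p)))
  }
})

test_that("doublets are channel-wise sums of their recorded parents", {
  cfg <- cohort_config(list(list(sample_id = "s1", n_events = 1000)),
                       doublet_rate = 0.1, seed = 3L)
  tb <- generate_event_cohort(cfg)$s1
  lab <- tb$truth$labels
  n_doub <- sum(lab == "doublet")
  # ~100 expected, binomial bounds
  expect_lt(abs(n_doub - 100), 3 * sqrt(1000 * 0.1 * 0.9))
  parents <- tb$truth$doublet_parents
  expect_equal(nrow(parents), n_doub)
  n_sing <- 1000 - n_doub
  for (i in seq_len(min(n_doub, 20))) {
    expect_equal(tb$values[n_sing + i, ],
                 tb$values[parents[i, 1], ] + tb$values[parents[i, 2], ])
  }
})

test_that("cohort generation validates fractions and channels", {
  bad <- list(population_spec("a", c(CD45 = 3), fraction = 0.6),
              population_spec("b", c(CD45 = 1), fraction = 0.6))
  cfg <- cohort_config(list(list(sample_id = "s1", n_events = 10)),
                       panel = "CD45", seed = 1L)
  expect_error(generate_event_cohort(cfg, bad), "sum to")
  ghost <- list(population_spec("a", c(CD999 = 3), fraction = 1))
  expect_error(generate_event_cohort(cfg, ghost), "unknown channel")
  expect_error(cohort_config(list(list(sample_id = "s", n_events = 10)),
                             doublet_rate = 0.5), "doublet_rate")
  expect_error(cohort_config(list(list(sample_id = "s", n_events = 10)),
                             panel = c("CD45", "CD45")), "unique")
})

test_that("cohort generation round-trips the transform and is reproducible", {
  cfg <- default_cohort_config(n_samples = 2, n_events = 400, seed = 9L)
  c1 <- generate_event_cohort(cfg)
  c2 <- generate_event_cohort(cfg)
  expect_identical(c1$S01$values, c2$S01$values)
  # events were drawn Gaussian on the arcsinh scale; transforming back must
  # reproduce that scale to high relative accuracy
  tr <- arcsinh_transform(c1$S01, cofactor = 150)
  back <- inverse_transform(tr)
  expect_lt(max(abs(back$values - c1$S01$values) /
                  pmax(abs(c1$S01$values), 1e-6)), 1e-6)
})

test_that("bulk mixtures are exact linear combinations before noise", {
  P <- cbind(A = c(10, 0, 5), B = c(0, 20, 5))
  rownames(P) <- c("g1", "g2", "g3")
  W1 <- matrix(c(1, 0), 1, dimnames = list("s1", c("A", "B")))
  m1 <- generate_bulk_mixtures(bulk_config(P, W1, noise_sd = 0, seed = 1L))
  expect_equal(unname(2^unclass(m1)[, 1] - 1), unname(P[, "A"]))
  W2 <- matrix(c(0.3, 0.7), 1, dimnames = list("s1", c("A", "B")))
  m2 <- generate_bulk_mixtures(bulk_config(P, W2, noise_sd = 0, seed = 1L))
  expect_equal(unname(2^unclass(m2)[, 1] - 1),
               unname(0.3 * P[, "A"] + 0.7 * P[, "B"]))
})

test_that("bulk mixtures are bit-reproducible under a fixed seed", {
  P <- synthetic_reference_profiles(n_genes = 120, markers_per_type = 20)
  W <- random_mixing_weights(5, seed = 2L)
  cfg <- bulk_config(P, W, noise_sd = 0.1, seed = 13L)
  expect_identical(unclass(generate_bulk_mixtures(cfg)),
                   unclass(generate_bulk_mixtures(cfg)))
})

test_that("bulk config rejects invalid weights and dimensions", {
  P <- cbind(A = c(1, 2), B = c(3, 4))
  rownames(P) <- c("g1", "g2")
  Wbad <- matrix(c(0.5, 0.2), 1, dimnames = list("s", c("A", "B")))
  expect_error(bulk_config(P, Wbad), "sum to 1")
  Wwrong <- matrix(c(1), 1, dimnames = list("s", "C"))
  expect_error(bulk_config(P, Wwrong), "mismatch")
})

test_that("single-cell generator plants mean shifts of the stated size", {
  ics <- list(P = sprintf("g%02d", 1:25))
  cfg <- sc_config(cell_types = c(myeloid = 300, other = 300),
                   gene_clusters = ics,
                   programs = list(list(cluster = "P", cell_types = "myeloid",
                                        shift = 2)),
                   baseline_mean = 3, baseline_sd = 0.4, seed = 21L)
  sc <- generate_sc_matrix(cfg)
  pg <- ics$P
  in_my <- sc$cell_types == "myeloid"
  diff <- mean(sc$values[pg, in_my]) - mean(sc$values[pg, !in_my])
  se <- 0.4 * sqrt(2 / (length(pg) * 300))
  expect_lt(abs(diff - 2), 3 * se)

  # zero shift: no expected difference
  cfg0 <- sc_config(cell_types = c(myeloid = 300, other = 300),
                    gene_clusters = ics,
                    programs = list(list(cluster = "P", cell_types = "myeloid",
                                         shift = 0)),
                    baseline_mean = 3, baseline_sd = 0.4, seed = 22L)
  sc0 <- generate_sc_matrix(cfg0)
  diff0 <- mean(sc0$values[pg, in_my]) - mean(sc0$values[pg, !in_my])
  expect_lt(abs(diff0), 3 * se)
})

test_that("planted high mitochondrial fractions fail downstream QC", {
  ics <- list(P = sprintf("g%02d", 1:250))
  cfg <- sc_config(cell_types = c(a = 40, b = 40), gene_clusters = ics,
                   programs = list(),
                   mito_fraction_range = c(0.06, 0.10), seed = 5L)
  sc <- generate_sc_matrix(cfg)
  expect_true(all(sc$mito_fractions >= 0.06 & sc$mito_fractions <= 0.10))
  expect_error(sc_qc_filter(sc$values, min_genes = 50), "QC removed everything")
})

test_that("sc config validates program references", {
  ics <- list(P = c("g1", "g2"))
  expect_error(sc_config(cell_types = c(a = 10), gene_clusters = ics,
                         programs = list(list(cluster = "Q", cell_types = "a",
                                              shift = 1))),
               "unknown gene cluster")
  expect_error(sc_config(cell_types = c(a = 10), gene_clusters = ics,
                         programs = list(list(cluster = "P", cell_types = "zz",
                                              shift = 1))),
               "unknown cell type")
})

test_that("planted-partition generator honors its contracts", {
  # p_in = 1, p_out = 0, two communities of 3: exactly two triangles
  g <- generate_planted_graph(2, 3, 1, 0, seed = 1L)
  expect_equal(nrow(g$edges), 6)
  expect_true(all(g$labels[g$edges$from] == g$labels[g$edges$to]))
  # reproducible edge set
  g1 <- generate_planted_graph(3, 50, 0.9, 0.02, seed = 7L)
  g2 <- generate_planted_graph(3, 50, 0.9, 0.02, seed = 7L)
  expect_identical(g1$edges, g2$edges)
  # precondition
  expect_error(generate_planted_graph(2, 3, 0.5, 0.5), "strictly smaller")
})
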