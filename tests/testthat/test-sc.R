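qc_fixture <- function() {
  # 300 genes x 12 cells; cell1 expresses only 150 genes; gene "rare" is
  # expressed in 2 cells; cells m1/m2 carry high mitochondrial load
  set.seed(61)
  genes <- c(sprintf("G%03d", 1:298), "rare", "MT-01")
  cells <- c("c150", sprintf("ok%02d", 1:9), "m1", "m2")
  v <- matrix(rexp(300 * 12) + 0.5, 300, 12, dimnames = list(genes, cells))
  v[151:300, "c150"] <- 0                 # 150 expressed genes
  v["rare", ] <- 0
  v["rare", c("ok01", "ok02")] <- 2       # expressed in 2 cells
  v["MT-01", ] <- 0.01
  v["MT-01", "m1"] <- 0.06 / 0.94 * sum(v[setdiff(genes, "MT-01"), "m1"])
  v["MT-01", "m2"] <- 0.049 / 0.951 * sum(v[setdiff(genes, "MT-01"), "m2"])
  v
}

test_that("QC applies the three filters strictly and in order", {
  v <- qc_fixture()
  res <- sc_qc_filter(v, min_genes = 200, min_cells = 3, max_mito = 0.05)
  expect_false("c150" %in% colnames(res$values))   # < 200 expressed genes
  expect_false("rare" %in% rownames(res$values))   # expressed in 2 cells
  expect_false("m1" %in% colnames(res$values))     # mito 0.06 >= 0.05
  expect_true("m2" %in% colnames(res$values))      # mito 0.049 < 0.05
  expect_equal(res$report$cells_in, 12)
  expect_equal(res$report$cells_after_gene_count, 11)
  expect_equal(res$report$cells_after_mito, 10)
})

test_that("per-type averages are plain means on the working scale", {
  v <- matrix(c(1, 3, 0, 5), 1, 4,
              dimnames = list("g", c("a1", "a2", "b1", "b2")))
  avg <- celltype_average(v, c(a1 = "A", a2 = "A", b1 = "B", b2 = "B"))
  expect_equal(unname(avg["g", ]), c(2, 2.5))
  single <- celltype_average(v[, 1, drop = FALSE], c(a1 = "A"))
  expect_equal(unname(single["g", "A"]), 1)
  allzero <- matrix(0, 1, 2, dimnames = list("z", c("a", "b")))
  expect_equal(unname(celltype_average(allzero, c("A", "B"))["z", ]), c(0, 0))
  expect_error(celltype_average(v, c("A", NA, "B", "B")), "labeled")
})

test_that("overexpression threshold is mean + 0.5 * sample SD, strict", {
  avg <- matrix(c(0, 2, 10), 1, 3,
                dimnames = list("g", c("t1", "t2", "t3")))
  calls <- overexpression_calls(avg)
  thr <- attr(calls, "thresholds")
  expect_equal(unname(thr["g"]), 4 + 0.5 * sqrt(28))
  expect_equal(unname(unclass(calls)["g", ]), c(0, 0, 1))
  avg2 <- matrix(c(0, 10), 1, 2, dimnames = list("g", c("t1", "t2")))
  calls2 <- overexpression_calls(avg2)
  expect_equal(unname(attr(calls2, "thresholds")["g"]), 5 + 0.5 * sqrt(50))
  expect_equal(unname(unclass(calls2)["g", ]), c(0, 1))
  # all averages equal: SD 0, strict > makes no call
  flat <- matrix(3, 1, 4, dimnames = list("g", paste0("t", 1:4)))
  expect_equal(sum(overexpression_calls(flat)), 0)
  expect_error(overexpression_calls(avg[, 1, drop = FALSE]), "at least 2")
})

test_that("the minimum-average type is never called when SD > 0", {
  set.seed(71)
  for (i in 1:20) {
    avg <- matrix(runif(5), 1, 5, dimnames = list("g", paste0("t", 1:5)))
    calls <- overexpression_calls(avg)
    expect_equal(unclass(calls)[1, which.min(avg)], 0)
  }
})

test_that("binary subclustering separates distinct call patterns", {
  calls <- rbind(g1 = c(1, 0), g2 = c(1, 0), g3 = c(0, 1), g4 = c(0, 1))
  colnames(calls) <- c("A", "B")
  asg <- binary_subcluster(calls, n_subclusters = 2)
  expect_equal(length(unique(asg)), 2)
  expect_equal(asg[["g1"]], asg[["g2"]])
  expect_equal(asg[["g3"]], asg[["g4"]])
  expect_true(asg[["g1"]] != asg[["g3"]])
  # identical patterns collapse to one subcluster with a note
  same <- rbind(g1 = c(1, 0), g2 = c(1, 0))
  colnames(same) <- c("A", "B")
  one <- binary_subcluster(same)
  expect_equal(unname(unique(one)), 1L)
  expect_match(attr(one, "note"), "identical")
  # 3 patterns, n = 2: complete linkage isolates the odd one out
  three <- rbind(g1 = c(1, 0), g2 = c(1, 0), g3 = c(0, 1))
  colnames(three) <- c("A", "B")
  asg3 <- binary_subcluster(three, n_subclusters = 2)
  expect_equal(asg3[["g1"]], asg3[["g2"]])
  expect_true(asg3[["g3"]] != asg3[["g1"]])
})

test_that("overexpressed fractions are per-subcluster column means", {
  calls <- rbind(g1 = c(1, 0), g2 = c(1, 0), g3 = c(0, 0), g4 = c(0, 0))
  colnames(calls) <- c("MG", "MDM")
  asg <- setNames(c(1L, 1L, 1L, 1L), rownames(calls))
  fr <- overexpression_fractions(asg, calls)
  expect_equal(unname(fr["1", ]), c(0.5, 0))
  none <- overexpression_fractions(asg, calls * 0)
  expect_true(all(none == 0))
})

test_that("DE threshold filter pins both strict cut-offs", {
  stats <- data.frame(gene = c("a", "b", "c", "d"),
                      logfc = c(0.3, 0.25, 0.5, 0.3),
                      p = c(1e-4, 1e-6, 0.001, 0.04))
  kept <- de_threshold_filter(stats, n_tests = 100)
  # a: adj p 0.01 < 0.05, logfc 0.3 > 0.25 -> kept
  # b: logfc exactly 0.25 -> dropped; c: adj p 0.1 -> dropped
  # d: adj p 1 -> dropped
  expect_equal(kept$gene, "a")
  expect_equal(kept$p_adjusted, 0.01)
  expect_error(de_threshold_filter(stats, n_tests = 2), "smaller than")
  bad <- stats; bad$p[1] <- 2
  expect_error(de_threshold_filter(bad, 100), "\\[0, 1\\]")
})

test_that("the full chain recovers planted programs across seeds", {
  ics <- list(ICa = sprintf("a%02d", 1:20), ICb = sprintf("b%02d", 1:20))
  for (seed in 1:5) {
    cfg <- sc_config(
      cell_types = c(myeloid = 150, lymphoid = 150, other = 150),
      gene_clusters = ics,
      programs = list(list(cluster = "ICa", cell_types = "myeloid", shift = 2),
                      list(cluster = "ICb", cell_types = "lymphoid", shift = 2)),
      baseline_mean = 2, baseline_sd = 0.4, n_extra_genes = 60,
      seed = 500L + seed)
    sc <- generate_sc_matrix(cfg)
    res <- sc_ic_analysis(sc$values, sc$cell_types, ics, min_genes = 20)
    for (pair in list(c("ICa", "myeloid"), c("ICb", "lymphoid"))) {
      fr <- res$fractions[[pair[1]]]
      top <- colnames(fr)[apply(fr, 1, which.max)]
      expect_true(pair[2] %in% top,
                  label = sprintf("seed %d, %s -> %s", seed, pair[1], pair[2]))
      # the planted subcluster is strongly called in its type, weakly elsewhere
      best_row <- which.max(fr[, pair[2]])
      expect_gte(fr[best_row, pair[2]], 0.9)
      expect_lte(max(fr[best_row, setdiff(colnames(fr), pair[2])]), 0.1)
    }
  }
})

test_that("rank-sum stand-in feeds the threshold filter sensibly", {
  set.seed(81)
  v <- rbind(up = c(rnorm(30, 4), rnorm(30, 1)),
             null = rnorm(60, 2))
  colnames(v) <- sprintf("c%02d", 1:60)
  de <- rank_sum_de(v, rep(c(TRUE, FALSE), each = 30))
  kept <- de_threshold_filter(de, n_tests = nrow(de))
  expect_true("up" %in% kept$gene)
  expect_false("null" %in% kept$gene)
})
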