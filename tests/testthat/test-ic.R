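test_that("variance filter removes strictly-below-threshold genes only", {
  m <- log2_expr(matrix(c(1, 1,       # variance 0
                          0, 1,       # variance 0.5
                          0, sqrt(0.1)),  # variance exactly 0.05
                        3, 2, byrow = TRUE,
                        dimnames = list(c("flat", "hot", "edge"),
                                        c("s1", "s2"))))
  f <- variance_filter(m, min_var = 0.05)
  expect_setequal(rownames(f), c("hot", "edge"))  # boundary gene kept
  allflat <- log2_expr(matrix(1, 2, 2, dimnames = list(c("a", "b"),
                                                       c("s1", "s2"))))
  expect_error(variance_filter(allflat), "every gene")
})

test_that("percentile clipping matches the interpolated-percentile formula", {
  x <- 1:100
  sc <- clip_scale_01(x)
  # linear-interpolation percentiles of 1..100: p2 = 2.98, p98 = 98.02
  expect_equal(quantile(x, 0.02, names = FALSE), 2.98)
  expect_equal(sc[1], 0)
  expect_equal(sc[100], 1)
  expect_equal(sc[50], (50 - 2.98) / (98.02 - 2.98), tolerance = 1e-12)
  expect_equal(clip_scale_01(c(0, 1)), c(0, 1))
  degen <- clip_scale_01(rep(3, 10))
  expect_true(all(is.na(degen)))
  expect_true(attr(degen, "degenerate"))
})

test_that("largest positive-correlation group is a maximum clique", {
  s <- seq(0, 1, length.out = 8)
  m <- rbind(g1 = s, g2 = s + 0.01, g3 = 1 - s)
  grp <- largest_positive_corr_group(m)
  expect_setequal(as.character(grp), c("g1", "g2"))
  # all mutually positive: whole cluster
  m2 <- rbind(g1 = s, g2 = s^1.2, g3 = s^0.8)
  expect_length(largest_positive_corr_group(m2), 3)
  # r(1,2) > 0, r(2,3) > 0, r(1,3) < 0: max clique size 2, lexicographic
  # tie-break keeps {g1, g2}
  v1 <- c(1, 2, 3, 4, 3)
  v2 <- c(1, 2, 3, 2, 4)
  v3 <- c(3, 2, 1, 2, 3.5)
  stopifnot(cor(v1, v2) > 0, cor(v2, v3) > 0, cor(v1, v3) < 0)
  grp3 <- largest_positive_corr_group(rbind(g1 = v1, g2 = v2, g3 = v3))
  expect_equal(as.character(grp3), c("g1", "g2"))
})

test_that("exact clique search matches exhaustive subset enumeration", {
  brute_force_group <- function(pos) {
    n <- nrow(pos)
    best <- integer(0)
    for (mask in 1:(2^n - 1)) {
      idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
      if (length(idx) <= length(best)) next
      if (all(pos[idx, idx])) best <- idx
    }
    best
  }
  for (seed in 1:6) {
    ngenes <- 6 + seed
    m <- phenotime:::with_seed(400L + seed,
                               matrix(rnorm(ngenes * 10), ngenes, 10))
    rownames(m) <- sprintf("g%02d", seq_len(ngenes))
    pos <- cor(t(m)) > 0
    diag(pos) <- TRUE
    expect_equal(length(largest_positive_corr_group(m)),
                 length(brute_force_group(pos)),
                 label = sprintf("fixture %d", seed))
  }
})

test_that("greedy fallback above the exact limit returns a valid group", {
  set.seed(9)
  base <- seq(0, 1, length.out = 12)
  m <- rbind(t(replicate(30, base + rnorm(12, 0, 0.1))),
             t(replicate(15, rev(base) + rnorm(12, 0, 0.1))))
  rownames(m) <- sprintf("g%02d", 1:45)
  grp <- largest_positive_corr_group(m, exact_limit = 20)
  expect_equal(attr(grp, "method"), "greedy")
  r <- cor(t(m[grp, ]))
  expect_true(all(r[upper.tri(r)] > 0))
  expect_gte(length(grp), 25)  # finds the large concordant block
})

test_that("anticorrelated-only clusters fall back to a single gene", {
  s <- seq(0, 1, length.out = 6)
  m <- rbind(g1 = s, g2 = 1 - s)
  grp <- largest_positive_corr_group(m)
  expect_length(grp, 1)
  expect_equal(attr(grp, "method"), "fallback")
})

test_that("activity is the scaled median of the selected group", {
  # two genes tracking each other: activity = median of the two scaled rows
  set.seed(44)
  v <- runif(10, 0, 5)
  bulk <- log2_expr(rbind(gA = v + rnorm(10, 0, 0.01), gB = v,
                          gC = rev(v)))
  colnames(bulk) <- sprintf("s%02d", 1:10)
  act <- ic_activity(bulk, list(IC1 = c("gA", "gB")))
  sA <- clip_scale_01(unclass(bulk)["gA", ])
  sB <- clip_scale_01(unclass(bulk)["gB", ])
  expect_equal(unname(unclass(act)["IC1", ]),
               unname(apply(rbind(sA, sB), 2, median)))
  expect_true(all(unclass(act) >= 0 & unclass(act) <= 1))
  # a cluster made of copies of one vector reproduces its scaled profile
  act2 <- ic_activity(log2_expr(rbind(gA = v, gB = v, gC = v)),
                      list(IC = c("gA", "gB", "gC")))
  expect_equal(unname(unclass(act2)[1, ]), unname(clip_scale_01(v)))
})

test_that("activity is invariant under rank-preserving affine rescaling", {
  set.seed(45)
  m <- matrix(runif(60, 1, 6), 6, 10,
              dimnames = list(sprintf("g%d", 1:6), sprintf("s%02d", 1:10)))
  ics <- list(IC = rownames(m))
  a1 <- ic_activity(log2_expr(m), ics)
  a2 <- ic_activity(log2_expr(3 * m + 2), ics)
  expect_equal(unclass(a1), unclass(a2), tolerance = 1e-9)
})

test_that("clusters with no surviving genes are flagged undefined", {
  bulk <- log2_expr(matrix(1, 2, 4, dimnames = list(c("g1", "g2"),
                                                    sprintf("s%d", 1:4))))
  act <- ic_activity(bulk, list(dead = c("g1", "g2"), ghost = "nope"))
  expect_setequal(attr(act, "undefined"), c("dead", "ghost"))
  expect_true(all(is.na(unclass(act))))
})

test_that("GMT files round-trip gene-cluster sets", {
  sets <- list(IC1 = c("A", "B", "C"), IC2 = c("D", "E"))
  f <- tempfile(fileext = ".gmt")
  write_gmt(sets, f)
  expect_equal(read_gmt(f), sets)
  writeLines("badline", f)
  expect_error(read_gmt(f), "malformed")
})
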