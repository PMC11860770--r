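test_that("Ward linkage merges within pairs before across pairs", {
  M <- rbind(c(0, 0), c(0.1, 0), c(10, 0), c(10.1, 0))
  tree <- ward_linkage(M)
  h <- tree$hclust$height
  # first two merges join the close pairs, the last joins the groups
  expect_lt(h[2], h[3])
  expect_equal(sort(cutree(tree$hclust, 2)), c(1, 1, 2, 2),
               ignore_attr = TRUE)
  # two nodes merge at their Euclidean distance (ward.D2 convention)
  t2 <- ward_linkage(rbind(c(0, 0), c(3, 4)))
  expect_equal(t2$hclust$height, 5)
  expect_error(ward_linkage(matrix(c(1, NaN), 2, 1)), "finite")
})

test_that("Ward merge heights are monotone on random codebooks", {
  with_seed_local(30, {
    for (i in 1:50) {
      M <- matrix(rnorm(20 * 4), 20, 4)
      h <- ward_linkage(M)$hclust$height
      expect_true(all(diff(h) >= -1e-12))
    }
  })
})

test_that("cut_clusters covers the degenerate cuts and orders by size", {
  with_seed_local(31, M <- matrix(rnorm(40), 10, 4))
  tree <- ward_linkage(M)
  expect_equal(cut_clusters(tree, 1), rep(1L, 10))
  expect_equal(sort(cut_clusters(tree, 10)), 1:10)
  expect_error(cut_clusters(tree, 0), "between")
  expect_error(cut_clusters(tree, 11), "between")
  lab <- cut_clusters(tree, 3)
  sizes <- tabulate(lab, 3)
  expect_true(all(diff(sizes) <= 0))  # label 1 is the largest cluster
})

test_that("a planted 3-group codebook is recovered exactly up to labels", {
  with_seed_local(32, {
    M <- rbind(matrix(rnorm(60, 0, 0.1), 15, 4),
               matrix(rnorm(48, 5, 0.1), 12, 4),
               matrix(rnorm(32, -5, 0.1), 8, 4))
  })
  truth <- rep(1:3, c(15, 12, 8))
  lab <- cut_clusters(ward_linkage(M), 3)
  # identical partition up to relabelling
  expect_equal(length(unique(paste(truth, lab))), 3L)
  # with the size convention the largest planted group is cluster 1
  expect_true(all(lab[1:15] == 1L))
})

test_that("Davies-Bouldin equals hand and brute-force evaluation", {
  # 1-D clusters {0,2} and {6,8}: S=1 each, centroid distance 6 -> 1/3
  M <- matrix(c(0, 2, 6, 8), 4, 1)
  expect_equal(davies_bouldin(M, c(1, 1, 2, 2)), 1 / 3)
  # two singletons -> zero scatter
  expect_equal(davies_bouldin(matrix(c(0, 1), 2, 1), c(1, 2)), 0)
  # identical centroids -> infinity sentinel
  expect_equal(davies_bouldin(matrix(c(0, 2, 0, 2), 4, 1), c(1, 1, 2, 2)),
               Inf)
  with_seed_local(33, {
    for (i in 1:25) {
      M <- matrix(rnorm(60), 20, 3)
      lab <- sample(1:4, 20, replace = TRUE)
      if (length(unique(lab)) < 2) next
      expect_equal(davies_bouldin(M, lab), brute_db(M, lab))
    }
  })
})

test_that("Davies-Bouldin improves when separation doubles", {
  with_seed_local(34, base <- matrix(rnorm(40, sd = 0.3), 20, 2))
  near <- base + rep(c(0, 3), each = 10)
  far <- base + rep(c(0, 6), each = 10)
  lab <- rep(1:2, each = 10)
  expect_lt(davies_bouldin(far, lab), davies_bouldin(near, lab))
})

test_that("select_k scans the full range and recovers planted regimes", {
  with_seed_local(35, {
    centers <- matrix(rnorm(30, sd = 4), 6, 5)
    M <- centers[rep(1:6, each = 12), ] + matrix(rnorm(72 * 5, sd = 0.2),
                                                 72, 5)
  })
  sol <- select_k(M, 2, 10)
  expect_equal(sol$k, 6L)
  expect_equal(nrow(sol$db_table), 9L)
  expect_true(all(sol$db_table$db >= 0))
  # centroids are exact member means
  for (g in seq_len(sol$k))
    expect_equal(sol$centroids[g, ], colMeans(M[sol$labels == g, ]))
  # invariant to variable permutation
  sol2 <- select_k(M[, c(3, 1, 5, 2, 4)], 2, 10)
  expect_equal(sol2$k, sol$k)
  expect_error(select_k(M, 1, 10), "kmin")
})

test_that("nearly identical nodes give a finite table and a valid choice", {
  with_seed_local(36, M <- matrix(1, 30, 4) + matrix(rnorm(120, sd = 1e-6),
                                                     30, 4))
  sol <- select_k(M, 2, 5)
  expect_true(all(is.finite(sol$db_table$db) | sol$db_table$db == Inf))
  expect_true(sol$k %in% 2:5)
})

test_that("cluster tests separate planted differences and respect Bonferroni", {
  with_seed_local(37, {
    M <- rbind(matrix(rnorm(100, 0), 25, 4),
               matrix(rnorm(100, 3), 25, 4),
               matrix(rnorm(100, 6), 25, 4))
  })
  lab <- rep(1:3, each = 25)
  ct <- cluster_tests(M, lab)
  expect_true(all(ct$kw_p < 0.001))
  expect_true(all(ct$table$p_bonferroni >= ct$table$p_raw, na.rm = TRUE))
  expect_true(all(ct$table$p_bonferroni <= 1, na.rm = TRUE))
  expect_equal(nrow(ct$table), 4 * 3)  # 4 variables x 3 pairs
  # duplicated clusters are indistinguishable after correction
  M2 <- rbind(M[1:25, ], M[1:25, ])
  ct2 <- cluster_tests(M2, rep(1:2, each = 25))
  expect_true(all(ct2$table$p_bonferroni == 1))
})

test_that("Kruskal-Wallis p-values are uniform under the null", {
  with_seed_local(38, {
    hits <- 0L
    reps <- 1000L
    for (i in seq_len(reps)) {
      M <- matrix(rnorm(30), 30, 1)
      p <- cluster_tests(M, rep(1:3, each = 10))$kw_p
      if (p < 0.05) hits <- hits + 1L
    }
  })
  expect_gt(hits / reps, 0.03)
  expect_lt(hits / reps, 0.07)
})
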