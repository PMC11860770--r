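test_that("uncertainty matrix is max(rel * x, floor)", {
  X <- matrix(c(100, 10, 50, 2), 2, 2)
  U <- build_uncertainties(X, rel = c(0.062, 0.10), floor = c(0.5, 0.3))
  expect_equal(U[1, 1], 6.2)       # relative branch
  expect_equal(U[2, 2], 0.3)       # floor branch (0.10 * 2 = 0.2 < 0.3)
  expect_equal(build_uncertainties(matrix(0, 1, 1), 0.1, 0.1)[1, 1], 0.1)
  # a zero concentration with zero floor violates strict positivity
  expect_error(build_uncertainties(matrix(c(0, 1), 1, 2), 0.1, 0),
               "positive floor")
  expect_error(build_uncertainties(matrix(-1, 1, 1), 0.1), "negative")
  # default floors keep U strictly positive even with zero concentrations
  with_seed_local(40, Xz <- matrix(rexp(50), 10, 5))
  Xz[1, ] <- 0
  expect_true(all(build_uncertainties(Xz, 0.1) > 0))
})

test_that("q_expected follows the degrees-of-freedom formula", {
  expect_equal(q_expected(902, 5, 4), 902 * 5 - 4 * (902 + 5))
  expect_equal(q_expected(902, 5, 4), 882)
  expect_error(q_expected(902, 5, 5), "overparameterized")
  expect_equal(q_expected(10, 4, 0), 40)
  qs <- sapply(1:3, function(k) q_expected(100, 5, k))
  expect_true(all(diff(qs) < 0))
})

test_that("rank-1 data yield the planted profile", {
  with_seed_local(41, {
    g <- rexp(30) + 0.1
    f <- c(0.1, 0.4, 0.3, 0.05, 0.15)
  })
  X <- outer(g, f)
  U <- 0.1 * X + 0.01
  fit <- fit_pmf(X, U, 1, n_starts = 5, seed = 1)
  cs <- sum(fit$F[1, ] * f) / sqrt(sum(fit$F[1, ]^2) * sum(f^2))
  expect_gte(cs, 0.999)
  expect_equal(rowSums(fit$F), 1, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("planted separable factors are recovered almost exactly", {
  # rank-3 nonnegative data in 5 variables, with near-pure rows present
  F0 <- rbind(c(0.7, 0.1, 0.1, 0.05, 0.05),
              c(0.05, 0.1, 0.7, 0.1, 0.05),
              c(0.05, 0.05, 0.1, 0.1, 0.7))
  with_seed_local(42, {
    G0 <- rbind(diag(3) * 10, matrix(rexp(90), 30, 3))
  })
  X <- G0 %*% F0
  U <- 0.1 * X + 1e-3
  fit <- fit_pmf(X, U, 3, n_starts = 10, seed = 2)
  expect_lt(fit$Q / fit$Q_expected, 0.01)
  expect_true(all(match_cosines(fit$F, F0) >= 0.99))
  expect_true(all(fit$G >= 0))
  expect_true(all(fit$F >= 0))
})

test_that("Q is non-increasing, exactly re-evaluable, and normalized", {
  with_seed_local(43, {
    for (s in 1:5) {
      X <- matrix(rexp(60), 12, 5)
      U <- 0.2 * X + 0.05
      fit <- suppressWarnings(fit_pmf(X, U, 3, n_starts = 4, seed = s,
                                      max_iter = 300))
      expect_true(all(diff(fit$q_trace) <= 1e-9 * pmax(fit$q_trace[-1], 1)))
      # independent re-evaluation of the reported Q
      expect_equal(fit$Q, brute_q(X, U, fit$G, fit$F),
                   tolerance = 1e-8)
      expect_equal(unname(rowSums(fit$F)), rep(1, 3), tolerance = 1e-9)
      expect_equal(fit$scaled_residuals, (X - fit$G %*% fit$F) / U)
    }
  })
})

test_that("fitting is deterministic given seed and start count", {
  with_seed_local(44, {
    X <- matrix(rexp(60), 12, 5)
    U <- 0.2 * X + 0.05
  })
  f1 <- fit_pmf(X, U, 2, n_starts = 4, seed = 7)
  f2 <- fit_pmf(X, U, 2, n_starts = 4, seed = 7)
  expect_identical(f1$G, f2$G)
  expect_identical(f1$F, f2$F)
  expect_identical(f1$Q, f2$Q)
})

test_that("fit_pmf guards its preconditions", {
  X <- matrix(rexp(20), 4, 5)
  U <- X * 0.1 + 0.1
  expect_error(fit_pmf(X - 10, U, 2), "nonnegative")
  expect_error(fit_pmf(X, U * 0, 2), "positive")
  expect_error(fit_pmf(X, U, 4), "k must satisfy")
  expect_warning(fit_pmf(X[c(1:4, 1:4), ], U[c(1:4, 1:4), ], 6,
                         n_starts = 2, max_iter = 50),
                 "overparameterized")
})

test_that("species percentages sum to 100 per variable", {
  with_seed_local(45, {
    X <- matrix(rexp(100), 20, 5)
    U <- 0.1 * X + 0.05
  })
  fit <- fit_pmf(X, U, 3, n_starts = 4, seed = 1)
  pct <- species_percent_profile(fit)
  expect_equal(unname(colSums(pct)), rep(100, 5), tolerance = 1e-6)
  # single factor -> all 100
  fit1 <- fit_pmf(X, U, 1, n_starts = 2, seed = 1)
  expect_equal(unname(species_percent_profile(fit1)[1, ]), rep(100, 5))
})

test_that("disjoint-support sources give a block-identity fingerprint", {
  F0 <- rbind(c(0.5, 0.5, 0, 0, 0),
              c(0, 0, 0.5, 0.5, 0),
              c(0, 0, 0, 0, 1))
  # include near-pure rows so the planted cone is identifiable
  with_seed_local(46, G0 <- rbind(diag(3) * 8,
                                  matrix(rexp(60) + 0.05, 20, 3)))
  X <- G0 %*% F0
  U <- 0.1 * X + 0.05
  fit <- fit_pmf(X, U, 3, n_starts = 10, seed = 3)
  pct <- species_percent_profile(fit)
  ord <- apply(cos_rows(fit$F, F0), 2, which.max)
  expect_gte(pct[ord[1], 1], 95); expect_gte(pct[ord[1], 2], 95)
  expect_gte(pct[ord[2], 3], 95); expect_gte(pct[ord[2], 4], 95)
  expect_gte(pct[ord[3], 5], 95)
})

test_that("top nodes and the cluster crosstab follow the quantile rule", {
  with_seed_local(47, G <- matrix(rexp(300), 100, 3))
  G[7, ] <- c(50, 0, 0)  # a pure factor-1 node
  fit <- structure(list(G = G, F = matrix(1 / 5, 3, 5), k = 3L),
                   class = "pmf_solution")
  tops <- top_nodes_per_factor(fit, q = 0.9)
  expect_true(7 %in% tops[[1]])
  expect_false(7 %in% tops[[2]] || 7 %in% tops[[3]])
  for (g in 1:3)
    expect_lte(abs(length(tops[[g]]) - 10), 2)
  labels <- rep(1:4, each = 25)
  xt <- factor_cluster_crosstab(fit, labels, q = 0.9)
  expect_equal(unname(rowSums(xt$counts)),
               sapply(tops, length))
  one <- factor_cluster_crosstab(fit, rep(1L, 100), q = 0.9)
  expect_true(all(one$percent[, 1] == 100))
  expect_error(factor_cluster_crosstab(fit, 1:5), "match")
})

test_that("bootstrap maps every factor on noiseless exact-rank data", {
  F0 <- rbind(c(0.6, 0.2, 0.1, 0.05, 0.05),
              c(0.05, 0.1, 0.2, 0.6, 0.05))
  with_seed_local(48, G0 <- matrix(rexp(80) + 0.1, 40, 2))
  X <- G0 %*% F0
  U <- 0.1 * X + 1e-3
  base <- fit_pmf(X, U, 2, n_starts = 6, seed = 5)
  bt <- bootstrap_pmf(X, U, base, n_boot = 30, seed = 6)
  expect_equal(bt$unmapped, 0L)
  expect_equal(bt$skipped, 0L)
  expect_equal(sum(bt$mapping_counts) + bt$unmapped, bt$n_effective * base$k)
  expect_true(all(bt$factor_mapping_rate == 1))
  expect_true(all(bt$iqr_coverage >= 0.8))
})
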