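test_that("linear initialization spans the leading PCA plane", {
  # data on an exact 2-D plane in 5-D
  with_seed_local(8, {
    s <- matrix(rnorm(400), 200, 2)
    V <- qr.Q(qr(matrix(rnorm(10), 5, 2)))
  })
  X <- s %*% t(V)
  g <- som_grid(8, 5)
  M <- linear_init(X, g)
  resid <- M - M %*% V %*% t(V)  # component outside the plane
  expect_lt(max(abs(resid)), 1e-8)
  # corner nodes attain the extreme PC1 scores among all nodes
  pc1 <- M %*% V[, 1]
  corner_ids <- c(1L, g$ydim, g$n_nodes - g$ydim + 1L, g$n_nodes)
  expect_true(all(range(pc1) %in% pc1[corner_ids]))
  # a single-row grid is a line along PC1
  M1 <- linear_init(X, som_grid(6, 1))
  R1 <- sweep(M1, 2, colMeans(X))
  v1 <- svd(sweep(X, 2, colMeans(X)), nu = 0, nv = 1)$v[, 1]
  expect_lt(max(abs(R1 - (R1 %*% v1) %*% t(v1))), 1e-8)
  expect_error(linear_init(matrix(1, 5, 3), som_grid(2, 2)), "rank 0")
})

test_that("batch SOM collapses onto duplicated data and stays in range", {
  r <- c(1, 2, 3, 4, 5)
  X <- matrix(r, 50, 5, byrow = TRUE) # all rows identical
  m0 <- train_batch_som(X, som_grid(3, 3), epochs = 5)
  expect_equal(m0$codebook, matrix(r, 9, 5, byrow = TRUE),
               ignore_attr = TRUE)
  expect_equal(m0$quality$qe, 0)
  # two distinct rows: codebook must stay within the data range
  X2 <- rbind(matrix(r, 25, 5, byrow = TRUE),
              matrix(r + 2, 25, 5, byrow = TRUE))
  m <- train_batch_som(X2, som_grid(3, 3), epochs = 20)
  for (j in 1:5)
    expect_true(all(m$codebook[, j] >= min(X2[, j]) - 1e-9 &
                      m$codebook[, j] <= max(X2[, j]) + 1e-9))
  expect_lt(m$quality$qe, 0.2)
})

test_that("training reduces the quantization error below the linear init", {
  with_seed_local(13, {
    X <- rbind(matrix(rnorm(400, 0), 80, 5),
               matrix(rnorm(400, 5), 80, 5))
  })
  g <- som_grid(6, 5)  # radius_init > radius_final: a real rough phase
  m <- train_batch_som(X, g, epochs = 30)
  qe_init <- mean(assign_bmu(linear_init(X, g), X)$qe)
  expect_lte(m$quality$qe, qe_init)
})

test_that("training is deterministic given identical inputs", {
  with_seed_local(14, X <- matrix(rnorm(300), 60, 5))
  m1 <- train_batch_som(X, som_grid(4, 4), epochs = 15, seed = 9)
  m2 <- train_batch_som(X, som_grid(4, 4), epochs = 15, seed = 9)
  expect_identical(m1$codebook, m2$codebook)
  expect_identical(m1$quality, m2$quality)
})

test_that("assign_bmu equals the exhaustive scan with lowest-index ties", {
  with_seed_local(15, {
    M <- matrix(rnorm(100), 20, 5)
    X <- matrix(rnorm(500), 100, 5)
  })
  a <- assign_bmu(M, X)
  for (i in seq_len(nrow(X))) {
    o <- brute_bmu(M, X[i, ])
    expect_identical(a$bmu[i], o$bmu)
    expect_identical(a$second[i], o$second)
    expect_equal(a$qe[i], o$qe)
  }
  # exact match
  a17 <- assign_bmu(M, M[17, , drop = FALSE])
  expect_identical(a17$bmu, 17L)
  expect_equal(a17$qe, 0)
  # equidistant nodes 3 and 9 -> node 3 wins
  M2 <- M
  M2[9, ] <- M2[3, ]
  x <- M2[3, ] + c(1, 0, 0, 0, 0)
  at <- assign_bmu(M2, matrix(x, 1))
  expect_identical(at$bmu, 3L)
  expect_identical(at$second, 9L)
  expect_error(assign_bmu(M, matrix(NA_real_, 1, 5)), "missing")
})

test_that("quality metrics follow their definitions", {
  with_seed_local(16, X <- matrix(rnorm(60), 12, 5))
  g <- som_grid(4, 3)
  model <- list(codebook = X, grid = g)  # codebook = the data itself
  q <- quality_metrics(model, X)
  expect_equal(q$qe, 0)
  expect_equal(q$dme, 0)
  expect_gte(q$te, 0); expect_lte(q$te, 1)
  # mean per-sample qe equals the overall qe
  with_seed_local(17, X2 <- matrix(rnorm(400), 80, 5))
  m <- train_batch_som(X2, g, epochs = 10)
  a <- assign_bmu(m$codebook, X2)
  expect_equal(mean(a$qe), m$quality$qe, tolerance = 1e-9)
})

test_that("u_matrix matches hand enumeration on a 3x3 grid", {
  g <- som_grid(3, 3)
  with_seed_local(18, M <- matrix(rnorm(27), 9, 3))
  u <- u_matrix(list(grid = g, codebook = M))
  for (i in 1:9) {
    nb <- hex3x3_neighbours[[i]]
    expect_equal(u[i],
                 mean(sapply(nb, function(j) sqrt(sum((M[i, ] - M[j, ])^2)))))
  }
  # constant codebook -> all zeros
  expect_equal(u_matrix(list(grid = g, codebook = matrix(1, 9, 3))),
               rep(0, 9))
  # one aberrant node has the largest value
  M2 <- matrix(0, 9, 3); M2[5, ] <- 10
  u2 <- u_matrix(list(grid = g, codebook = M2))
  expect_equal(which.max(u2), 5L)
})

test_that("QE outlier rule is a scale-free Tukey fence", {
  a <- structure(list(qe = rep(2, 10)), class = "bmu_assignment")
  expect_false(any(detect_qe_outliers(a)))
  with_seed_local(19, qe <- c(rexp(100), 50))
  a2 <- structure(list(qe = qe), class = "bmu_assignment")
  f1 <- detect_qe_outliers(a2)
  expect_true(f1[101])
  # invariant under common positive rescaling
  a3 <- structure(list(qe = qe * 37.5), class = "bmu_assignment")
  expect_identical(detect_qe_outliers(a3), f1)
  expect_error(detect_qe_outliers(structure(list(qe = 1:3),
                                            class = "bmu_assignment")),
               "4 samples")
})

test_that("map selection prefers low te among near-minimal qe", {
  with_seed_local(20, X <- matrix(rnorm(500), 100, 5))
  sel <- select_som(X, list(som_grid(3, 2), som_grid(4, 3)), epochs = 10)
  expect_equal(nrow(sel$table), 2L)
  expect_equal(sum(sel$table$selected), 1L)
  ok <- sel$table$qe <= min(sel$table$qe) * 1.05
  pick <- which(sel$table$selected)
  expect_true(ok[pick])
  expect_equal(sel$table$te[pick], min(sel$table$te[ok]))
})
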