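# Independent brute-force oracles, written against the definitions, not the
# package internals.

# nearest / second nearest node by explicit scan, strict-< tie-breaking
brute_bmu <- function(M, x) {
  best <- 1L; second <- NA_integer_
  dbest <- Inf; dsecond <- Inf
  for (i in seq_len(nrow(M))) {
    d <- sqrt(sum((x - M[i, ])^2))
    if (d < dbest) {
      dsecond <- dbest; second <- best
      dbest <- d; best <- i
    } else if (d < dsecond) {
      dsecond <- d; second <- i
    }
  }
  list(bmu = best, second = second, qe = dbest)
}

# Davies-Bouldin by direct evaluation of the formula
brute_db <- function(M, labels) {
  ids <- sort(unique(labels))
  k <- length(ids)
  cent <- matrix(0, k, ncol(M))
  S <- numeric(k)
  for (i in seq_len(k)) {
    rows <- which(labels == ids[i])
    for (j in seq_len(ncol(M))) cent[i, j] <- mean(M[rows, j])
    dd <- 0
    for (r in rows) dd <- dd + sqrt(sum((M[r, ] - cent[i, ])^2))
    S[i] <- dd / length(rows)
  }
  worst <- numeric(k)
  for (i in seq_len(k)) {
    best <- -Inf
    for (j in seq_len(k)) {
      if (i == j) next
      Mij <- sqrt(sum((cent[i, ] - cent[j, ])^2))
      best <- max(best, (S[i] + S[j]) / Mij)
    }
    worst[i] <- best
  }
  mean(worst)
}

# PMF objective by explicit double loop
brute_q <- function(X, U, G, F) {
  GF <- G %*% F
  total <- 0
  for (i in seq_len(nrow(X)))
    for (j in seq_len(ncol(X)))
      total <- total + ((X[i, j] - GF[i, j]) / U[i, j])^2
  total
}

# hand-enumerated hex neighbour lists for a 3 x 3 grid (column-major ids,
# odd 0-based columns shifted down by 0.5)
hex3x3_neighbours <- list(
  c(2, 4), c(1, 3, 4, 5), c(2, 5, 6),
  c(1, 2, 5, 7, 8), c(2, 3, 4, 6, 8, 9), c(3, 5, 9),
  c(4, 8), c(4, 5, 7, 9), c(5, 6, 8))

# cosine similarity matrix between row sets
cos_rows <- function(A, B) {
  A <- A / sqrt(rowSums(A^2))
  B <- B / sqrt(rowSums(B^2))
  A %*% t(B)
}

# greedy one-to-one matching of recovered factors to planted profiles,
# returning the matched cosine per planted profile
match_cosines <- function(F_hat, P) {
  cm <- cos_rows(F_hat, P)
  out <- stats::setNames(numeric(ncol(cm)), colnames(cm))
  for (step in seq_len(ncol(cm))) {
    ij <- which(cm == max(cm), arr.ind = TRUE)[1L, ]
    out[ij[2L]] <- cm[ij[1L], ij[2L]]
    cm[ij[1L], ] <- -Inf
    cm[, ij[2L]] <- -Inf
  }
  out
}

# write a small panel CSV and return its path
write_toy_csv <- function(lines, path = tempfile(fileext = ".csv")) {
  writeLines(lines, path)
  path
}

# a tiny complete panel: n_hours per site, deterministic values
make_small_panel <- function(sites = c("A1", "B1"), n_hours = 6L,
                             seed = 42L) {
  ts <- sprintf("2020-03-0%dT%02d:00", 1 + (seq_len(n_hours) - 1) %/% 24,
                (seq_len(n_hours) - 1) %% 24)
  site <- rep(sites, each = n_hours)
  stamp <- rep(ts, times = length(sites))
  X <- with_seed_local(seed, matrix(runif(length(site) * 5, 1, 10),
                                    ncol = 5))
  aq_panel(stamp, site, X)
}

with_seed_local <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}
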