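# Independent oracles: straightforward reimplementations of each formula
# chain, kept deliberately naive (per-edge / per-cell loops, no shared code
# with the package internals beyond the public per-edge terms).

# per-edge index summation straight from the graph, bypassing edge_partition()
oracle_index <- function(g, id) {
  em <- g$edges
  deg <- tabulate(c(em[, 1], em[, 2]) + 1L, nbins = g$n_vertices)
  total <- 0
  for (i in seq_len(nrow(em))) {
    a <- deg[em[i, 1] + 1L]; b <- deg[em[i, 2] + 1L]
    term <- switch(id,
      M1 = a + b, M2 = a * b, H = 2 / (a + b), HM = (a + b)^2,
      F = a^2 + b^2, ABC = sqrt((a + b - 2) / (a * b)),
      R = 1 / sqrt(a * b), SC = 1 / sqrt(a + b),
      GA = 2 * sqrt(a * b) / (a + b), SO = sqrt(a^2 + b^2),
      N = sqrt(a + b))
    total <- total + term
  }
  total
}

oracle_all_indices <- function(g) {
  sapply(index_ids(), oracle_index, g = g)
}

# ordinary least squares via the normal equations
oracle_ols <- function(X, y) {
  Xi <- cbind(1, as.matrix(X))
  drop(solve(t(Xi) %*% Xi, t(Xi) %*% y))
}

# TOPSIS by explicit loops over the five stages
oracle_topsis <- function(m, w) {
  n <- nrow(m); k <- ncol(m)
  r <- m
  for (j in 1:k) r[, j] <- m[, j] / sqrt(sum(m[, j]^2))
  v <- r
  for (j in 1:k) v[, j] <- w[j] * r[, j]
  ideal <- apply(v, 2, max); anti <- apply(v, 2, min)
  dp <- dm <- numeric(n)
  for (i in 1:n) {
    dp[i] <- sqrt(sum((v[i, ] - ideal)^2))
    dm[i] <- sqrt(sum((v[i, ] - anti)^2))
  }
  C <- dm / (dp + dm)
  list(Dplus = dp, Dminus = dm, C = C)
}

# VIKOR by explicit loops
oracle_vikor <- function(m, w, v = 0.5) {
  n <- nrow(m); k <- ncol(m)
  fb <- apply(m, 2, max); fw <- apply(m, 2, min)
  S <- R <- numeric(n)
  for (i in 1:n) {
    t <- numeric(k)
    for (j in 1:k)
      t[j] <- if (fb[j] == fw[j]) 0 else w[j] * (fb[j] - m[i, j]) / (fb[j] - fw[j])
    S[i] <- sum(t); R[i] <- max(t)
  }
  Q <- v * (S - min(S)) / (max(S) - min(S)) +
    (1 - v) * (R - min(R)) / (max(R) - min(R))
  list(S = S, R = R, Q = Q)
}

# small seeded graph pool reused by property-style tests
pool_graphs <- function(n, sizes = 6:20, seed0 = 100) {
  lapply(seq_len(n), function(i)
    random_molecular_graph(sizes[1 + (i - 1) %% length(sizes)],
                           extra_edge_prob = 0.2, seed = seed0 + i))
}

with_seed <- function(seed, code) withr::with_seed(seed, code)
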