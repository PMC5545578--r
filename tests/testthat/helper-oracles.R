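# Independent brute-force oracles used to validate the graph-metric code.
# They deliberately share no code with the package implementation.

# All-pairs shortest path lengths by exhaustive simple-path enumeration.
oracle_shortest_paths <- function(W, rule = "inverse") {
  n <- nrow(W)
  len <- function(w) if (rule == "inverse") 1 / w else -log(w)
  L <- matrix(Inf, n, n)
  diag(L) <- 0
  paths_from <- function(cur, target, visited, acc) {
    if (cur == target) return(acc)
    best <- Inf
    for (nxt in seq_len(n)) {
      if (!visited[nxt] && W[cur, nxt] > 0) {
        v2 <- visited; v2[nxt] <- TRUE
        best <- min(best, paths_from(nxt, target, v2, acc + len(W[cur, nxt])))
      }
    }
    best
  }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j) {
      vis <- rep(FALSE, n); vis[i] <- TRUE
      L[i, j] <- paths_from(i, j, vis, 0)
    }
  }
  L
}

oracle_global_efficiency <- function(W, rule = "inverse") {
  n <- nrow(W)
  L <- oracle_shortest_paths(W, rule)
  s <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && is.finite(L[i, j])) s <- s + 1 / L[i, j]
  }
  s / (n * (n - 1))
}

oracle_nodal_efficiency <- function(W, rule = "inverse") {
  n <- nrow(W)
  L <- oracle_shortest_paths(W, rule)
  sapply(seq_len(n), function(i) {
    s <- 0
    for (j in seq_len(n)) if (j != i && is.finite(L[i, j])) s <- s + 1 / L[i, j]
    s / (n - 1)
  })
}

oracle_local_efficiency <- function(W, rule = "inverse") {
  n <- nrow(W)
  vals <- sapply(seq_len(n), function(i) {
    nb <- which(W[i, ] > 0)
    if (length(nb) < 2) return(0)
    oracle_global_efficiency(W[nb, nb, drop = FALSE], rule)
  })
  mean(vals)
}

# Hand-coded Benjamini-Hochberg step-up rejection mask.
oracle_bh_mask <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- 0
  for (i in seq_len(m)) if (ps[i] <= i * q / m) k <- i
  mask <- rep(FALSE, m)
  if (k > 0) mask[o[seq_len(k)]] <- TRUE
  mask
}

# random symmetric weight matrix with given edge density, weights in (0, 1]
random_weight_matrix <- function(n, density = 0.5) {
  W <- matrix(0, n, n)
  ut <- upper.tri(W)
  on <- runif(sum(ut)) < density
  w <- numeric(sum(ut))
  w[on] <- runif(sum(on), 0.05, 1)
  W[ut] <- w
  W + t(W)
}

# enumerate every symmetric graph on n nodes with edge weights drawn from a
# fixed grid (0 = absent); returns a list of matrices
enumerate_grid_graphs <- function(n, grid) {
  npairs <- n * (n - 1) / 2
  combos <- expand.grid(rep(list(grid), npairs))
  lapply(seq_len(nrow(combos)), function(r) {
    W <- matrix(0, n, n)
    W[upper.tri(W)] <- as.numeric(combos[r, ])
    W + t(W)
  })
}
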