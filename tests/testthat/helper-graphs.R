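# Independent brute-force graph oracles used to validate the metric engine.
# All deliberately naive: matrix-power reachability, walk-count shortest-path
# enumeration, exhaustive triangle counts - no shared code with the package.

sym_adj <- function(n, edges) {
  a <- matrix(0L, n, n)
  if (length(edges)) {
    e <- matrix(edges, ncol = 2, byrow = TRUE)
    a[e] <- 1L; a[e[, c(2, 1), drop = FALSE]] <- 1L
  }
  a
}

path_graph <- function(n) sym_adj(n, unlist(lapply(seq_len(n - 1),
                                                   function(i) c(i, i + 1))))
cycle_graph <- function(n) {
  a <- path_graph(n); a[1, n] <- a[n, 1] <- 1L; a
}
complete_graph <- function(n) {
  a <- matrix(1L, n, n); diag(a) <- 0L; a
}
star_graph <- function(n_leaves) sym_adj(n_leaves + 1,
  unlist(lapply(seq_len(n_leaves) + 1, function(i) c(1, i))))

# hop distances via boolean matrix powers: d(i,j) = min k with (A^k)[i,j] > 0
oracle_distances <- function(adj) {
  n <- nrow(adj)
  D <- matrix(Inf, n, n); diag(D) <- 0
  P <- diag(n)
  for (k in seq_len(n - 1)) {
    P <- P %*% adj
    newly <- is.infinite(D) & P > 0
    D[newly] <- k
  }
  D
}

# number of shortest paths: walks of length d(i,j) are exactly the shortest
# paths (any shorter walk would imply a smaller distance)
oracle_path_counts <- function(adj, D) {
  n <- nrow(adj)
  pows <- vector("list", n - 1)
  P <- diag(n)
  for (k in seq_len(n - 1)) { P <- P %*% adj; pows[[k]] <- P }
  S <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    d <- D[i, j]
    if (i != j && is.finite(d)) S[i, j] <- pows[[d]][i, j]
  }
  S
}

oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  D <- oracle_distances(adj)
  S <- oracle_path_counts(adj, D)
  bc <- numeric(n)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    if (!is.finite(D[s, t])) next
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      if (is.finite(D[s, v]) && is.finite(D[v, t]) &&
          D[s, v] + D[v, t] == D[s, t])
        bc[v] <- bc[v] + S[s, v] * S[v, t] / S[s, t]
    }
  }
  if (n > 2) bc / ((n - 1) * (n - 2) / 2) else bc
}

oracle_clustering <- function(adj) {
  n <- nrow(adj)
  tri <- diag(adj %*% adj %*% adj) / 2
  k <- rowSums(adj)
  ifelse(k < 2, 0, 2 * tri / (k * (k - 1)))
}

oracle_global_eff <- function(adj) {
  D <- oracle_distances(adj)
  n <- nrow(D)
  if (n < 2) return(0)
  inv <- 1 / D; diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

oracle_nodal_eff <- function(adj) {
  D <- oracle_distances(adj)
  n <- nrow(D)
  inv <- 1 / D; diag(inv) <- 0
  rowSums(inv) / (n - 1)
}

oracle_cpl <- function(adj) {
  D <- oracle_distances(adj)
  d <- D[row(D) != col(D)]
  mean(d[is.finite(d)])
}

oracle_local_eff <- function(adj) {
  n <- nrow(adj)
  sapply(seq_len(n), function(i) {
    nb <- which(adj[i, ] > 0)
    if (length(nb) < 2) return(0)
    oracle_global_eff(adj[nb, nb, drop = FALSE])
  })
}

is_connected <- function(adj) all(is.finite(oracle_distances(adj)))

# every labeled graph on n nodes (n <= 5), as a list of adjacency matrices
all_labeled_graphs <- function(n) {
  pairs <- t(combn(n, 2))
  m <- nrow(pairs)
  lapply(0:(2^m - 1), function(mask) {
    on <- which(bitwAnd(mask, 2^(seq_len(m) - 1)) > 0)
    sym_adj(n, t(pairs[on, , drop = FALSE]))
  })
}

random_graph <- function(n, p, seed) {
  set.seed(seed)
  a <- matrix(0L, n, n)
  up <- upper.tri(a)
  a[up] <- rbinom(sum(up), 1, p)
  a[lower.tri(a)] <- t(a)[lower.tri(a)]
  a
}

random_connected_graph <- function(n, p, seed) {
  for (k in 0:200) {
    a <- random_graph(n, p, seed + 7919 * k)
    if (is_connected(a)) return(a)
  }
  stop("failed to sample a connected graph")
}

# Watts-Strogatz: ring lattice with k neighbours per side, rewire prob p
ws_graph <- function(n, k_half, p, seed) {
  set.seed(seed)
  a <- matrix(0L, n, n)
  for (i in seq_len(n)) for (s in seq_len(k_half)) {
    j <- ((i - 1 + s) %% n) + 1
    a[i, j] <- a[j, i] <- 1L
  }
  if (p > 0) {
    for (i in seq_len(n)) for (s in seq_len(k_half)) {
      if (runif(1) < p) {
        j <- ((i - 1 + s) %% n) + 1
        cand <- which(a[i, ] == 0 & seq_len(n) != i)
        if (length(cand)) {
          jn <- cand[sample.int(length(cand), 1)]
          a[i, j] <- a[j, i] <- 0L
          a[i, jn] <- a[jn, i] <- 1L
        }
      }
    }
  }
  a
}

# small synthetic cohort shared by several tests (cheap but realistic)
tiny_cohort <- function(n_hc = 10, n_patient = 6, seed = 123, ...) {
  generate_cohort(synthetic_config(n_hc = n_hc, n_patient = n_patient,
                                   seed = seed, ...))
}
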