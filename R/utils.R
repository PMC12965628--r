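# Internal helpers: deterministic seed derivation and input validation.

# Stable 31-bit hash of character labels, used to derive per-stage /
# per-subject seeds from one master seed. Polynomial rolling hash over UTF-8
# bytes mod the Mersenne prime 2^31 - 1, kept in double precision (exact:
# intermediate products stay below 2^53), so the result is a valid R integer
# seed and independent of R's RNG state.
hash31 <- function(...) {
  txt <- paste(vapply(list(...), as.character, character(1)), collapse = "\r")
  bytes <- utf8ToInt(txt)
  h <- 17
  for (b in bytes) h <- (h * 1048573 + b) %% 2147483647
  as.integer(h)
}

#' Derive a reproducible sub-seed from a master seed and labels
#'
#' All stochastic stages of the pipeline draw their seeds through this
#' function, so that e.g. adding subjects to a cohort does not reshuffle
#' the randomness of existing subjects.
#'
#' @param master integer master seed.
#' @param ... labels (stage name, subject id, density, ...) identifying the
#'   stream.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master, ...) {
  stopifnot(is.numeric(master), length(master) == 1, is.finite(master))
  m <- abs(as.numeric(master)) %% 2147483647
  as.integer((as.numeric(hash31(...)) + m * 1048573) %% 2147483647)
}

# Validate a binary symmetric zero-diagonal adjacency matrix.
check_adjacency <- function(adj, caller = "graph metric") {
  if (!is.matrix(adj) || nrow(adj) != ncol(adj))
    stop(caller, ": adjacency must be a square matrix", call. = FALSE)
  if (any(adj != 0 & adj != 1))
    stop(caller, ": adjacency must be binary (0/1)", call. = FALSE)
  if (any(diag(adj) != 0))
    stop(caller, ": adjacency must have a zero diagonal (no self-loops)",
         call. = FALSE)
  if (!isTRUE(all.equal(adj, t(adj))))
    stop(caller, ": adjacency must be symmetric (undirected graph)",
         call. = FALSE)
  storage.mode(adj) <- "integer"
  adj
}

# upper-triangle edge list (1-based, i < j) of a binary adjacency
adj_to_edges <- function(adj) {
  idx <- which(upper.tri(adj) & adj != 0, arr.ind = TRUE)
  idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
}

edges_to_adj <- function(edges, n) {
  adj <- matrix(0L, n, n)
  if (nrow(edges)) {
    adj[cbind(edges[, 1], edges[, 2])] <- 1L
    adj[cbind(edges[, 2], edges[, 1])] <- 1L
  }
  adj
}
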