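# Independent oracles used to cross-check the implementation.
# These deliberately avoid igraph and the package's own code paths:
# Floyd-Warshall for shortest paths, recursive DFS for reachability, and a
# truncated Taylor series for the matrix exponential.

# Shortest directed path lengths under edge lengths 1/weight.
# A[i, j] = weight of edge j -> i; returns D[u, v] = length of shortest
# path u -> v (Inf if unreachable), diagonal 0.
oracle_shortest_paths <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (A[i, j] > 0) D[j, i] <- 1 / A[i, j] # edge j -> i
  }
  diag(D) <- 0
  for (k in seq_len(n)) for (u in seq_len(n)) for (v in seq_len(n)) {
    if (D[u, k] + D[k, v] < D[u, v]) D[u, v] <- D[u, k] + D[k, v]
  }
  D
}

oracle_average_efficiency <- function(A) {
  n <- nrow(A)
  D <- oracle_shortest_paths(A)
  tot <- 0
  for (u in seq_len(n)) for (v in seq_len(n)) {
    if (u != v && is.finite(D[u, v])) tot <- tot + 1 / D[u, v]
  }
  tot / (n * (n - 1))
}

# Reachability by recursive DFS on the edge relation (paths of length >= 1).
# Returns a logical matrix R[u, v]; R[u, u] is TRUE iff u lies on a cycle.
oracle_reachability <- function(A) {
  n <- nrow(A)
  R <- matrix(FALSE, n, n)
  for (s in seq_len(n)) {
    visited <- logical(n)
    stack <- which(A[, s] > 0) # heads of edges leaving s
    while (length(stack)) {
      u <- stack[[1]]
      stack <- stack[-1]
      if (!visited[u]) {
        visited[u] <- TRUE
        stack <- c(stack, which(A[, u] > 0))
      }
    }
    R[s, ] <- visited
  }
  R
}

oracle_connected_pairs <- function(A) {
  sum(oracle_reachability(A))
}

# Truncated Taylor sum of exp(M); enough terms for ||M|| of small fixtures.
oracle_expm_taylor <- function(M, terms = 60) {
  n <- nrow(M)
  acc <- diag(n)
  term <- diag(n)
  for (k in seq_len(terms)) {
    term <- term %*% M / k
    acc <- acc + term
  }
  acc
}

# Random spatial digraph on few nodes with weights bounded away from 0.
random_small_graph <- function(n, m = NULL) {
  if (is.null(m)) m <- sample(seq_len(n * (n - 1)), 1)
  k <- sample.int(n * (n - 1), m)
  jj <- (k - 1L) %/% (n - 1L) + 1L
  r <- (k - 1L) %% (n - 1L) + 1L
  ii <- r + (r >= jj)
  A <- matrix(0, n, n)
  A[cbind(ii, jj)] <- runif(m, 0.2, 2)
  th <- runif(n, 0, 2 * pi)
  rad <- sqrt(runif(n))
  spatial_digraph(A, cbind(rad * cos(th), rad * sin(th)))
}
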