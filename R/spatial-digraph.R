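#' Construct a spatially embedded weighted digraph
#'
#' The core container of the package: an `n x n` non-negative adjacency
#' matrix together with 2-D node coordinates on the closed unit disk.
#' Entry `A[i, j]` is the weight of the directed edge `j -> i` (rows are
#' in-links; see the package help page for the convention).
#'
#' @param adjacency Square numeric matrix of non-negative finite weights
#'   with a zero diagonal.
#' @param coordinates Numeric matrix with one row per node and two columns;
#'   every row must have Euclidean norm at most 1.
#' @return An object of class `spatial_digraph` with fields `adjacency`,
#'   `coordinates`, `n` (node count) and `m` (number of positive entries).
#' @examples
#' A <- matrix(0, 2, 2); A[1, 2] <- 1   # edge 2 -> 1
#' g <- spatial_digraph(A, rbind(c(0, 0), c(0.5, 0)))
#' g$m
#' @export
spatial_digraph <- function(adjacency, coordinates) {
  adjacency <- as.matrix(adjacency)
  coordinates <- as.matrix(coordinates)
  g <- structure(
    list(
      adjacency = adjacency,
      coordinates = coordinates,
      n = nrow(adjacency),
      m = sum(adjacency > 0)
    ),
    class = "spatial_digraph"
  )
  validate_spatial_digraph(g)
  g
}

#' Validate the invariants of a spatial digraph
#'
#' Checks squareness, zero diagonal, non-negative finite weights, agreement
#' of the stored edge count with the number of positive entries, and that
#' all coordinates lie in the closed unit disk.
#'
#' @param g A `spatial_digraph`.
#' @param tol Numerical slack allowed on the unit-disk constraint.
#' @return `g`, invisibly; errors if any invariant is violated.
#' @export
validate_spatial_digraph <- function(g, tol = 1e-12) {
  A <- g$adjacency
  if (!is.matrix(A) || nrow(A) != ncol(A)) {
    stop("adjacency must be a square matrix", call. = FALSE)
  }
  if (!all(is.finite(A))) stop("adjacency contains non-finite weights", call. = FALSE)
  if (any(A < 0)) stop("adjacency contains negative weights", call. = FALSE)
  if (any(diag(A) != 0)) stop("self-loops are not allowed (non-zero diagonal)", call. = FALSE)
  if (g$n != nrow(A)) stop("node count does not match adjacency dimension", call. = FALSE)
  if (g$m != sum(A > 0)) stop("edge count does not match positive entries", call. = FALSE)
  xy <- g$coordinates
  if (!is.matrix(xy) || nrow(xy) != g$n || ncol(xy) != 2L) {
    stop("coordinates must be an n x 2 matrix", call. = FALSE)
  }
  if (!all(is.finite(xy))) stop("coordinates contain non-finite values", call. = FALSE)
  if (any(sqrt(rowSums(xy^2)) > 1 + tol)) {
    stop("coordinates must lie within the closed unit disk", call. = FALSE)
  }
  invisible(g)
}

#' @export
print.spatial_digraph <- function(x, ...) {
  cat(sprintf(
    "<spatial_digraph>  n = %d nodes, m = %d directed edges, total weight = %.4f\n",
    x$n, x$m, sum(x$adjacency)
  ))
  invisible(x)
}

#' Specify the edge-weight distribution
#'
#' Weights are drawn from the chosen family, non-positive draws are replaced
#' by `clamp_value`, and the sample is then rescaled so the weight sum equals
#' the edge count (division by the sample mean). The default
#' `Normal(1, 0.25^2)` with clamp 0.05 is the distribution used for all
#' shipped experiment defaults; a lognormal family is available with
#' user-supplied parameters.
#'
#' @param family `"normal"` or `"lognormal"`.
#' @param location Mean (normal) or log-mean (lognormal).
#' @param scale Standard deviation (normal) or log-sd (lognormal); must be > 0.
#' @param clamp_value Positive replacement for non-positive draws.
#' @return A `weight_spec` object.
#' @export
weight_spec <- function(family = c("normal", "lognormal"),
                        location = 1, scale = 0.25, clamp_value = 0.05) {
  family <- match.arg(family)
  if (!is.numeric(scale) || scale <= 0) stop("scale must be > 0", call. = FALSE)
  if (!is.numeric(clamp_value) || clamp_value <= 0) stop("clamp_value must be > 0", call. = FALSE)
  structure(
    list(family = family, location = location, scale = scale, clamp_value = clamp_value),
    class = "weight_spec"
  )
}

#' Draw and normalize a sequence of edge weights
#'
#' Draws `m` weights from the family in `spec`, replaces any draw `<= 0`
#' with the clamp value (before normalization), and rescales so the sum of
#' the returned weights equals `m` exactly, i.e. divides by the sample mean.
#'
#' @param m Number of weights (edge count), at least 1.
#' @param spec A [weight_spec()].
#' @return Numeric vector of `m` strictly positive weights summing to `m`.
#' @export
sample_and_normalize_weights <- function(m, spec = weight_spec()) {
  if (!inherits(spec, "weight_spec")) stop("spec must be a weight_spec", call. = FALSE)
  if (m < 1) stop("m must be >= 1", call. = FALSE)
  w <- switch(spec$family,
    normal = rnorm(m, mean = spec$location, sd = spec$scale),
    lognormal = rlnorm(m, meanlog = spec$location, sdlog = spec$scale)
  )
  w[w <= 0] <- spec$clamp_value
  w * (m / sum(w))
}

#' Place nodes uniformly on the unit disk
#'
#' Uniform by area: radius `sqrt(U)`, angle `2*pi*U`, so the expected
#' distance from the origin is 2/3.
#'
#' @param n Number of nodes.
#' @return An `n x 2` coordinate matrix.
#' @export
embed_nodes_unit_disk <- function(n) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  r <- sqrt(runif(n))
  theta <- 2 * pi * runif(n)
  cbind(x = r * cos(theta), y = r * sin(theta))
}

#' Generate a random spatially embedded weighted digraph
#'
#' Edges are assigned to `m` ordered node pairs sampled uniformly without
#' replacement from all `n(n-1)` loopless pairs; weights are drawn and
#' normalized per [sample_and_normalize_weights()]; coordinates per
#' [embed_nodes_unit_disk()]. Uses the current RNG state: call `set.seed()`
#' first for reproducibility. Draw order is fixed (pairs, weights,
#' coordinates).
#'
#' @param n Node count, at least 2.
#' @param m Edge count, `0 < m <= n*(n-1)`.
#' @param weights A [weight_spec()].
#' @return A [spatial_digraph()].
#' @examples
#' set.seed(1)
#' g <- generate_random_digraph(100, 912)
#' sum(g$adjacency)   # normalized weights sum to m
#' @export
generate_random_digraph <- function(n, m, weights = weight_spec()) {
  if (n < 2) stop("n must be >= 2", call. = FALSE)
  if (m < 1 || m > n * (n - 1)) {
    stop(sprintf("m must satisfy 0 < m <= n(n-1) = %d", n * (n - 1)), call. = FALSE)
  }
  # index k enumerates off-diagonal cells column-wise: column j holds the
  # n-1 possible heads of edges leaving tail j
  k <- sample.int(n * (n - 1), m)
  jj <- (k - 1L) %/% (n - 1L) + 1L
  r <- (k - 1L) %% (n - 1L) + 1L
  ii <- r + (r >= jj)
  w <- sample_and_normalize_weights(m, weights)
  A <- matrix(0, n, n)
  A[cbind(ii, jj)] <- w
  spatial_digraph(A, embed_nodes_unit_disk(n))
}

#' In- or out-neighborhood of a node
#'
#' For `side = "in"` the members are the tails of the edges pointing at `v`;
#' for `side = "out"` the heads of the edges leaving `v`. The complement is
#' the rest of the node set excluding `v` itself.
#'
#' @param g A `spatial_digraph`.
#' @param v Node index.
#' @param side `"in"` or `"out"`.
#' @return List with `node`, `side`, `members`, `complement` (integer vectors).
#' @export
neighborhood <- function(g, v, side = c("in", "out")) {
  side <- match.arg(side)
  if (v < 1 || v > g$n) stop("invalid node index", call. = FALSE)
  members <- if (side == "in") which(g$adjacency[v, ] > 0) else which(g$adjacency[, v] > 0)
  structure(
    list(
      node = as.integer(v), side = side,
      members = as.integer(members),
      complement = setdiff(seq_len(g$n), c(as.integer(v), members))
    ),
    class = "neighborhood_view"
  )
}

#' Node strength (sum of in- or out-link weights)
#'
#' @inheritParams neighborhood
#' @return Non-negative scalar.
#' @export
strength <- function(g, v, side = c("in", "out")) {
  side <- match.arg(side)
  if (v < 1 || v > g$n) stop("invalid node index", call. = FALSE)
  if (side == "in") sum(g$adjacency[v, ]) else sum(g$adjacency[, v])
}

#' Conservation fingerprint of a digraph
#'
#' A compact summary — node count, edge count, sorted weight multiset and
#' coordinates — of exactly the quantities every rewiring step must
#' preserve. Two graphs related by any sequence of legal swaps compare
#' `identical()` on their fingerprints.
#'
#' @param g A `spatial_digraph`.
#' @return A list with `n`, `m`, `weights` (sorted) and `coordinates`.
#' @export
graph_fingerprint <- function(g) {
  list(
    n = g$n, m = g$m,
    weights = sort(g$adjacency[g$adjacency > 0]),
    coordinates = g$coordinates
  )
}
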