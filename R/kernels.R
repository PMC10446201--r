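# Consensus / advection kernels.
#
# The in-degree Laplacian L_in = D_in - A generates consensus dynamics
# x'(t) = -L_in x(t): nodes relax toward the states of their in-neighbors
# and the kernel exp(-t L_in) has unit row sums. The out-degree Laplacian
# L_out = D_out - A generates advection x'(t) = -L_out x(t): concentration
# is transported along edges and exp(-t L_out) has unit column sums (total
# concentration is conserved). Kernel entry (i, j) measures the signal flow
# from node j to node i over the interval t via all paths, so it is
# positive exactly when j can reach i.

# internal: Laplacian from a raw adjacency matrix
.laplacian <- function(A, flavor) {
  if (flavor == "in") diag(rowSums(A)) - A else diag(colSums(A)) - A
}

# internal: kernel from a raw adjacency matrix, with negativity guard.
# Matrix exponentials of -tL are provably non-negative; entries below
# -`tol` indicate numerical failure, larger ones are rounding noise.
.kernel <- function(A, flavor, t, tol = 1e-9) {
  L <- .laplacian(A, if (flavor == "consensus") "in" else "out")
  K <- expm_dense(-t * L)
  mn <- min(K)
  if (!all(is.finite(K))) stop("matrix exponential produced non-finite entries", call. = FALSE)
  if (mn < -tol) {
    stop(sprintf("kernel has negative entries beyond tolerance (min %.3e)", mn), call. = FALSE)
  }
  if (mn < 0) K[K < 0] <- 0
  K
}

#' In- or out-degree Laplacian of a digraph
#'
#' `flavor = "in"` returns `D_in - A` with `D_in = diag(in-strengths)`
#' (rows sum to zero); `flavor = "out"` returns `D_out - A` with
#' `D_out = diag(out-strengths)` (columns sum to zero).
#'
#' @param g A [spatial_digraph()].
#' @param flavor `"in"` or `"out"`.
#' @return An `n x n` matrix.
#' @export
digraph_laplacian <- function(g, flavor = c("in", "out")) {
  flavor <- match.arg(flavor)
  .laplacian(g$adjacency, flavor)
}

#' Consensus or advection kernel of a digraph
#'
#' The matrix exponential `exp(-t * L_in)` (consensus) or `exp(-t * L_out)`
#' (advection). Entry `(i, j)` quantifies the proportion of signal flow
#' from node `j` to node `i` over the interval `t`; it is strictly positive
#' exactly when a directed path (possibly of length 0) leads from `j` to
#' `i`. Consensus kernels have unit row sums, advection kernels unit column
#' sums. Tiny negative rounding noise (within `tol`) is clamped to zero;
#' anything larger raises an error.
#'
#' @param g A [spatial_digraph()].
#' @param flavor `"consensus"` or `"advection"`.
#' @param t Non-negative rewiring interval (default 1).
#' @param tol Entrywise negativity tolerance.
#' @return An `n x n` kernel matrix.
#' @examples
#' g <- make_fixture("two-node-single-edge")
#' flow_kernel(g, "consensus", t = 1)   # [[e^-1, 1 - e^-1], [0, 1]]
#' @export
flow_kernel <- function(g, flavor = c("consensus", "advection"), t = 1, tol = 1e-9) {
  flavor <- match.arg(flavor)
  if (t < 0) stop("t must be >= 0", call. = FALSE)
  .kernel(g$adjacency, flavor, t, tol)
}

#' Evolve node concentrations over an interval
#'
#' Applies the chosen kernel to an initial concentration vector:
#' `x(t) = exp(-t L) x(0)`.
#'
#' @param g A [spatial_digraph()].
#' @param x0 Numeric vector of length `n`.
#' @param t Non-negative interval.
#' @param flavor `"consensus"` or `"advection"`.
#' @return Numeric vector of length `n`.
#' @export
evolve_concentrations <- function(g, x0, t = 1, flavor = c("consensus", "advection")) {
  flavor <- match.arg(flavor)
  if (length(x0) != g$n) stop("x0 must have length n", call. = FALSE)
  drop(flow_kernel(g, flavor, t) %*% x0)
}

#' In-flow profile of a node
#'
#' Row `v` of the consensus kernel without the diagonal entry: the intensity
#' of signal flow from every other node into `v` over the interval `t`.
#' These are the values the functional principle uses when rewiring an
#' in-link of `v`.
#'
#' @param g A [spatial_digraph()].
#' @param v Node index.
#' @param t Non-negative interval.
#' @return Named numeric vector over the nodes `u != v`.
#' @export
inflow_profile <- function(g, v, t = 1) {
  if (v < 1 || v > g$n) stop("invalid node index", call. = FALSE)
  K <- flow_kernel(g, "consensus", t)
  setNames(K[v, -v], seq_len(g$n)[-v])
}

#' Out-flow profile of a node
#'
#' Column `v` of the advection kernel without the diagonal entry: the
#' intensity of signal flow from `v` to every other node over the interval
#' `t`. Used by the functional principle when rewiring an out-link of `v`.
#'
#' @inheritParams inflow_profile
#' @return Named numeric vector over the nodes `u != v`.
#' @export
outflow_profile <- function(g, v, t = 1) {
  if (v < 1 || v > g$n) stop("invalid node index", call. = FALSE)
  K <- flow_kernel(g, "advection", t)
  setNames(K[-v, v], seq_len(g$n)[-v])
}
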