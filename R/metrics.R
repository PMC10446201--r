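# Network measures for evolved digraphs.
#
# All measures treat the network as directed; path-based measures use the
# topological edge length 1/weight (strong links are easy to traverse).

# internal: pairwise reachability with directed paths of length >= 1.
# Returns R[u, v] = TRUE iff a path u -> v exists (diagonal FALSE), plus a
# per-node flag for membership in a directed cycle (self-connectivity).
.reachability <- function(A) {
  ig <- igraph::graph_from_adjacency_matrix(t(A) > 0, mode = "directed")
  D <- igraph::distances(ig, mode = "out", weights = NA)
  R <- is.finite(D) & D > 0
  n <- nrow(A)
  self <- logical(n)
  for (i in seq_len(n)) {
    outs <- which(A[, i] > 0) # heads of edges leaving i
    self[i] <- length(outs) > 0L && any(R[outs, i] | outs == i)
  }
  list(reach = R, self_cycle = self)
}

#' Topological length of an edge
#'
#' The difficulty of transmission along a link: `1/weight`.
#'
#' @param w Positive edge weight.
#' @return `1/w`.
#' @export
topological_length <- function(w) {
  if (any(w <= 0)) stop("weights must be > 0", call. = FALSE)
  1 / w
}

#' Average efficiency of a digraph
#'
#' Mean inverse shortest directed path length over all ordered node pairs
#' `i != j`, under edge lengths `1/weight`; unreachable pairs contribute 0.
#'
#' @param g A [spatial_digraph()].
#' @return Non-negative scalar.
#' @examples
#' average_efficiency(make_fixture("three-cycle")) # 0.75
#' @export
average_efficiency <- function(g) {
  n <- g$n
  if (g$m == 0) return(0)
  ig <- as_igraph(g)
  D <- igraph::distances(ig, mode = "out", weights = 1 / igraph::E(ig)$weight)
  inv <- 1 / D
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

#' Number of connected ordered node pairs
#'
#' Counts ordered pairs `(i, j)` — including `i = j` — joined by a directed
#' path of length at least 1. A self-pair counts exactly when the node lies
#' on a directed cycle, so the upper bound `n^2` is attained by strongly
#' connected graphs.
#'
#' @param g A [spatial_digraph()].
#' @param proportion Logical: return the count divided by `n^2`?
#' @return Integer count (or proportion in `[0, 1]`).
#' @export
connected_pairs <- function(g, proportion = FALSE) {
  r <- .reachability(g$adjacency)
  count <- sum(r$reach) + sum(r$self_cycle)
  if (proportion) count / g$n^2 else as.integer(count)
}

#' Find convergent or divergent hubs
#'
#' Convergent hubs have an in-degree above the threshold and at least one
#' out-link (they pool information and pass it on); divergent hubs have an
#' out-degree above the threshold and at least one in-link. Degrees are
#' binary link counts, not strengths. "Above" is a strict inequality by
#' default (`threshold = 15` means degree >= 16); set `strict = FALSE` for
#' an inclusive reading.
#'
#' @param g A [spatial_digraph()].
#' @param threshold Positive integer degree threshold (default 15).
#' @param kind `"convergent"` or `"divergent"`.
#' @param strict Logical: use `>` (default) rather than `>=`.
#' @return Integer vector of node indices.
#' @export
find_hubs <- function(g, threshold = 15L, kind = c("convergent", "divergent"),
                      strict = TRUE) {
  kind <- match.arg(kind)
  if (threshold < 1) stop("threshold must be >= 1", call. = FALSE)
  P <- g$adjacency > 0
  indeg <- rowSums(P)
  outdeg <- colSums(P)
  above <- function(x) if (strict) x > threshold else x >= threshold
  if (kind == "convergent") {
    which(above(indeg) & outdeg >= 1)
  } else {
    which(above(outdeg) & indeg >= 1)
  }
}

#' Find convergent-divergent units
#'
#' A convergent-divergent unit is an ordered pair of distinct hubs — a
#' convergent hub `c` and a divergent hub `d` — joined by a directed path
#' from `c` to `d`. Each unit carries its source nodes (`u != c` that reach
#' `c`), target nodes (`u != d` reached from `d`) and intermediate nodes
#' (nodes other than the hubs that are reached from `c` and reach `d`,
#' i.e. lie on at least one directed walk between the hubs), together with
#' the size and binary density of the induced intermediate subgraph.
#'
#' @inheritParams find_hubs
#' @return List of `convergent_divergent_unit` objects (possibly empty).
#' @export
find_cdus <- function(g, threshold = 15L, strict = TRUE) {
  A <- g$adjacency
  n <- g$n
  conv <- find_hubs(g, threshold, "convergent", strict)
  divg <- find_hubs(g, threshold, "divergent", strict)
  if (length(conv) == 0L || length(divg) == 0L) return(list())
  R <- .reachability(A)$reach
  units <- list()
  for (c_hub in conv) {
    for (d_hub in divg) {
      if (c_hub == d_hub || !R[c_hub, d_hub]) next
      intermediate <- setdiff(which(R[c_hub, ] & R[, d_hub]), c(c_hub, d_hub))
      unit <- structure(
        list(
          convergent_hub = c_hub,
          divergent_hub = d_hub,
          source_nodes = setdiff(which(R[, c_hub]), c_hub),
          target_nodes = setdiff(which(R[d_hub, ]), d_hub),
          intermediate_nodes = intermediate,
          n = n
        ),
        class = "convergent_divergent_unit"
      )
      st <- intermediate_subgraph_stats(g, unit)
      unit$intermediate_size_proportion <- st$size_proportion
      unit$intermediate_density <- st$density
      units[[length(units) + 1L]] <- unit
    }
  }
  units
}

#' Size and density of a unit's intermediate subgraph
#'
#' Size proportion is `|intermediate| / n`. Density is the binary edge
#' density of the induced subgraph, `edges / (k (k - 1))`, defined only for
#' `k >= 2` intermediate nodes (`NA` otherwise; such units are excluded
#' from density aggregation).
#'
#' @param g A [spatial_digraph()].
#' @param unit A `convergent_divergent_unit` for `g`.
#' @return List with `size_proportion` and `density`.
#' @export
intermediate_subgraph_stats <- function(g, unit) {
  S <- unit$intermediate_nodes
  k <- length(S)
  density <- if (k >= 2) {
    sub <- g$adjacency[S, S, drop = FALSE]
    sum(sub > 0) / (k * (k - 1))
  } else {
    NA_real_
  }
  list(size_proportion = k / g$n, density = density)
}

#' Aggregate source/target/overlap proportions over units
#'
#' Per unit the proportions are `|S|/n`, `|T|/n` and `|S intersect T|/n`;
#' the aggregate is their mean over the supplied units. An empty unit list
#' yields `NA`s (the quantity is undefined when no unit exists).
#'
#' @param units List of `convergent_divergent_unit` objects.
#' @return List with `source_proportion`, `target_proportion`,
#'   `overlap_proportion`.
#' @export
source_target_overlap <- function(units) {
  if (length(units) == 0L) {
    return(list(source_proportion = NA_real_, target_proportion = NA_real_,
                overlap_proportion = NA_real_))
  }
  props <- vapply(units, function(u) {
    c(length(u$source_nodes), length(u$target_nodes),
      length(intersect(u$source_nodes, u$target_nodes))) / u$n
  }, numeric(3))
  list(
    source_proportion = mean(props[1, ]),
    target_proportion = mean(props[2, ]),
    overlap_proportion = mean(props[3, ])
  )
}

# internal: directed weighted modularity of a given partition
# (Leicht-Newman objective with a resolution parameter)
.directed_modularity <- function(A, membership, resolution = 1) {
  mtot <- sum(A)
  if (mtot == 0) return(0)
  sin_ <- rowSums(A)
  sout <- colSums(A)
  q <- 0
  for (cc in unique(membership)) {
    idx <- membership == cc
    q <- q + sum(A[idx, idx]) / mtot -
      resolution * sum(sin_[idx]) * sum(sout[idx]) / mtot^2
  }
  q
}

# internal: deterministic greedy agglomerative optimizer. Starts from
# singletons and repeatedly merges the community pair with the largest
# positive modularity gain (first maximum in row-major order on ties).
.greedy_partition <- function(A, resolution = 1) {
  n <- nrow(A)
  mtot <- sum(A)
  membership <- seq_len(n)
  if (mtot == 0 || n < 2) return(membership)
  E <- A # E[a, b]: total weight of edges from community b to community a
  sin_ <- rowSums(A)
  sout <- colSums(A)
  active <- rep(TRUE, n)
  repeat {
    idx <- which(active)
    if (length(idx) < 2L) break
    Ei <- E[idx, idx, drop = FALSE]
    gain <- (Ei + t(Ei)) / mtot -
      resolution * (outer(sin_[idx], sout[idx]) + outer(sout[idx], sin_[idx])) / mtot^2
    diag(gain) <- -Inf
    best <- which.max(gain)
    if (gain[best] <= 1e-12) break
    ab <- arrayInd(best, dim(gain))
    a <- idx[ab[1]]
    b <- idx[ab[2]]
    E[a, ] <- E[a, ] + E[b, ]
    E[, a] <- E[, a] + E[, b]
    E[b, ] <- 0
    E[, b] <- 0
    sin_[a] <- sin_[a] + sin_[b]
    sout[a] <- sout[a] + sout[b]
    membership[membership == b] <- a
    active[b] <- FALSE
  }
  match(membership, unique(membership))
}

#' Directed weighted modularity with a greedy partition
#'
#' Optimizes the directed weighted (Leicht-Newman style) modularity
#' objective by a deterministic greedy agglomeration from singleton
#' communities, and evaluates the objective on the resulting partition. A
#' user-supplied membership vector skips the optimization and scores that
#' partition instead. The routine is deterministic (first-maximum
#' tie-break), so repeated calls agree exactly.
#'
#' @param g A [spatial_digraph()].
#' @param resolution Resolution parameter scaling the null term (default 1).
#' @param membership Optional integer community labels to score directly.
#' @return List with `modularity`, `membership` and `n_communities`.
#' @export
modularity_score <- function(g, resolution = 1, membership = NULL) {
  A <- g$adjacency
  if (is.null(membership)) {
    membership <- .greedy_partition(A, resolution)
  } else if (length(membership) != g$n) {
    stop("membership must have length n", call. = FALSE)
  }
  list(
    modularity = .directed_modularity(A, membership, resolution),
    membership = membership,
    n_communities = length(unique(membership))
  )
}

#' Binary density of the whole digraph
#'
#' `m / (n (n - 1))`: the fraction of possible loopless directed edges
#' present. Reference line for intermediate-subgraph densities.
#'
#' @param g A [spatial_digraph()].
#' @return Scalar in `[0, 1]`.
#' @export
graph_density <- function(g) {
  g$m / (g$n * (g$n - 1))
}

#' Compute the full metric suite for a digraph
#'
#' One-row data frame with the measures tracked along rewiring
#' trajectories. Metric groups can be switched off for speed:
#' `"connectivity"` (proportion of connected pairs, average efficiency),
#' `"hubs"` (hub proportions), `"cdu"` (unit counts and
#' source/target/overlap/intermediate statistics, aggregated over units),
#' `"modularity"`, and `"spatial"` (mean Euclidean edge length and mean
#' cosine of edges to the field, evaluated at each edge's tail; `NA` when
#' `field = "none"`).
#'
#' @param g A [spatial_digraph()].
#' @param hub_threshold Degree threshold for hubs (default 15).
#' @param field `"lateral"`, `"radial"`, or `"none"` (for the edge-cosine
#'   summary only).
#' @param include Character vector of metric groups.
#' @return One-row `data.frame`; omitted groups are `NA`.
#' @export
compute_metrics <- function(g, hub_threshold = 15L,
                            field = c("lateral", "radial", "none"),
                            include = c("connectivity", "hubs", "cdu",
                                        "modularity", "spatial")) {
  field <- match.arg(field)
  n <- g$n
  A <- g$adjacency
  out <- data.frame(
    step = NA_integer_,
    proportion_connected_pairs = NA_real_,
    average_efficiency = NA_real_,
    convergent_hub_proportion = NA_real_,
    divergent_hub_proportion = NA_real_,
    cdu_count = NA_integer_,
    cdu_present = NA,
    source_proportion = NA_real_,
    target_proportion = NA_real_,
    overlap_proportion = NA_real_,
    intermediate_size_proportion = NA_real_,
    intermediate_density = NA_real_,
    modularity = NA_real_,
    mean_edge_length = NA_real_,
    mean_edge_cosine = NA_real_
  )
  if ("connectivity" %in% include) {
    out$proportion_connected_pairs <- connected_pairs(g, proportion = TRUE)
    out$average_efficiency <- average_efficiency(g)
  }
  if ("hubs" %in% include) {
    out$convergent_hub_proportion <- length(find_hubs(g, hub_threshold, "convergent")) / n
    out$divergent_hub_proportion <- length(find_hubs(g, hub_threshold, "divergent")) / n
  }
  if ("cdu" %in% include) {
    units <- find_cdus(g, hub_threshold)
    out$cdu_count <- length(units)
    out$cdu_present <- length(units) > 0L
    sto <- source_target_overlap(units)
    out$source_proportion <- sto$source_proportion
    out$target_proportion <- sto$target_proportion
    out$overlap_proportion <- sto$overlap_proportion
    if (length(units)) {
      out$intermediate_size_proportion <-
        mean(vapply(units, `[[`, numeric(1), "intermediate_size_proportion"))
      dens <- vapply(units, `[[`, numeric(1), "intermediate_density")
      out$intermediate_density <- if (all(is.na(dens))) NA_real_ else mean(dens, na.rm = TRUE)
    }
  }
  if ("modularity" %in% include) {
    out$modularity <- modularity_score(g)$modularity
  }
  if ("spatial" %in% include && g$m > 0) {
    edges <- which(A > 0, arr.ind = TRUE) # [, 1] head i, [, 2] tail j
    xy <- g$coordinates
    ex <- xy[edges[, 1], 1] - xy[edges[, 2], 1]
    ey <- xy[edges[, 1], 2] - xy[edges[, 2], 2]
    d <- sqrt(ex^2 + ey^2)
    out$mean_edge_length <- mean(d)
    if (field != "none") {
      fx <- if (field == "lateral") rep(1, nrow(edges)) else xy[edges[, 2], 1]
      fy <- if (field == "lateral") rep(0, nrow(edges)) else xy[edges[, 2], 2]
      fn <- sqrt(fx^2 + fy^2)
      cosv <- (ex * fx + ey * fy) / (d * fn)
      cosv[!is.finite(cosv)] <- 0
      out$mean_edge_cosine <- mean(cosv)
    }
  }
  out
}
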