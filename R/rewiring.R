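# Rewiring engine.
#
# One rewiring step: (1) draw r1 ~ U[0,1] to pick the side (in-link if
# r1 < p_in), then a pivot v uniformly among nodes whose degree on that
# side is in {1, ..., n-2}; (2) draw r2 ~ U[0,1] to pick the principle,
# partitioning [0,1) in the order distance | wave | functional | random;
# (3) the principle picks a member k to cut and a complement node l to add,
# and the removed edge's weight transfers to the new edge; (4) repeat for M
# steps. A single RNG stream drives every draw in the fixed order
# r1, pivot, r2, principle-specific draws.

#' Configuration of a rewiring run
#'
#' @param p_in Probability of rewiring an in-link at each step (out-link
#'   with probability `1 - p_in`).
#' @param p_function,p_distance,p_wave Probabilities of the functional,
#'   distance and wave principles; their sum must be at most 1 and the
#'   remainder `p_random = 1 - p_function - p_distance - p_wave` is assigned
#'   to uniform random rewiring (the baseline functional+random algorithm
#'   uses `p_distance = p_wave = 0`).
#' @param mode Functional rule variant: `"deterministic"` (argmin cut /
#'   argmax add on kernel values) or `"stochastic"` (cut probability
#'   proportional to 1/value, add probability proportional to value).
#' @param field Vector field for the wave principle: `"lateral"` is the
#'   constant field (1, 0), `"radial"` points away from the origin,
#'   `"none"` disables the field (only valid when `p_wave = 0`).
#' @param t Kernel interval between rewiring steps (default 1).
#' @param steps Number of rewiring steps M.
#' @param seed Integer seed for the run's RNG stream.
#' @return A `rewiring_config` object.
#' @export
rewiring_config <- function(p_in = 0.5, p_function = 1, p_distance = 0, p_wave = 0,
                            mode = c("deterministic", "stochastic"),
                            field = c("lateral", "radial", "none"),
                            t = 1, steps = 15000L, seed = 1L) {
  mode <- match.arg(mode)
  field <- match.arg(field)
  probs <- c(p_in = p_in, p_function = p_function, p_distance = p_distance, p_wave = p_wave)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]", call. = FALSE)
  if (p_function + p_distance + p_wave > 1 + 1e-12) {
    stop("p_function + p_distance + p_wave must be <= 1", call. = FALSE)
  }
  if (field == "none" && p_wave > 0) stop("p_wave > 0 requires a field", call. = FALSE)
  if (t < 0) stop("t must be >= 0", call. = FALSE)
  if (steps < 0) stop("steps must be >= 0", call. = FALSE)
  structure(
    list(
      p_in = p_in, p_function = p_function, p_distance = p_distance,
      p_wave = p_wave, p_random = max(0, 1 - p_function - p_distance - p_wave),
      mode = mode, field = field, t = t, steps = as.integer(steps),
      seed = as.integer(seed)
    ),
    class = "rewiring_config"
  )
}

# internal constructor for a swap record
.edge_swap <- function(pivot, side, removed, added, weight, principle) {
  structure(
    list(
      pivot = as.integer(pivot), side = side, removed = as.integer(removed),
      added = as.integer(added), weight = weight, principle = principle
    ),
    class = "edge_swap"
  )
}

# internal: member / complement index sets on the raw adjacency
.members <- function(A, v, side) {
  if (side == "in") which(A[v, ] > 0) else which(A[, v] > 0)
}

#' Select the pivot node and rewiring side for one step
#'
#' Draws `r1 ~ U[0,1]`; the side is `"in"` when `r1 < p_in`. The pivot is
#' then uniform among nodes whose degree on that side lies in
#' `{1, ..., n-2}` (so that both a removable link and a free slot exist).
#' If no node on the drawn side is eligible an error of class
#' `adaptrewire_no_eligible_pivot` is raised rather than silently switching
#' sides.
#'
#' @param g A [spatial_digraph()].
#' @param p_in Probability of the in side.
#' @return List with `node` and `side`.
#' @export
select_pivot <- function(g, p_in = 0.5) {
  side <- if (runif(1) < p_in) "in" else "out"
  A <- g$adjacency
  deg <- if (side == "in") rowSums(A > 0) else colSums(A > 0)
  eligible <- which(deg >= 1 & deg <= g$n - 2L)
  if (length(eligible) == 0L) {
    stop(structure(
      class = c("adaptrewire_no_eligible_pivot", "error", "condition"),
      list(message = sprintf("no node with %s-degree in {1, ..., n-2}", side), call = NULL)
    ))
  }
  list(node = resample1(eligible), side = side)
}

#' Choose the rewiring principle for one step
#'
#' Draws `r2 ~ U[0,1]` and partitions the unit interval in the order
#' distance, wave, functional, random with the configured probabilities.
#'
#' @param config A [rewiring_config()].
#' @return One of `"distance"`, `"wave"`, `"functional"`, `"random"`.
#' @export
choose_principle <- function(config) {
  r2 <- runif(1)
  .principle_from_r2(r2, config)
}

.principle_from_r2 <- function(r2, config) {
  if (r2 < config$p_distance) return("distance")
  if (r2 < config$p_distance + config$p_wave) return("wave")
  if (r2 < config$p_distance + config$p_wave + config$p_function) return("functional")
  "random"
}

# ---- principle workers on raw matrices ------------------------------------

# deterministic: cut the tied-minimum, add the tied-maximum (uniform among
# ties); stochastic: cut with probability ~ 1/value, add with ~ value.
# Zero kernel values dominate the stochastic cut rule (1/0 = Inf), so the
# cut is uniform among zero-valued members when any exist; an all-zero
# complement makes the add uniform.
.functional_kl <- function(A, v, side, t, mode) {
  K <- .kernel(A, if (side == "in") "consensus" else "advection", t)
  members <- .members(A, v, side)
  complement <- setdiff(seq_len(nrow(A)), c(v, members))
  vm <- if (side == "in") K[v, members] else K[members, v]
  vc <- if (side == "in") K[v, complement] else K[complement, v]
  if (mode == "deterministic") {
    k <- resample1(members[vm == min(vm)])
    l <- resample1(complement[vc == max(vc)])
  } else {
    zero <- vm <= 0
    if (any(zero)) {
      k <- resample1(members[zero])
    } else {
      inv <- 1 / vm
      if (any(is.infinite(inv))) {
        k <- resample1(members[is.infinite(inv)])
      } else {
        k <- members[sample.int(length(members), 1L, prob = inv)]
      }
    }
    if (sum(vc) <= 0) {
      l <- resample1(complement)
    } else {
      l <- complement[sample.int(length(complement), 1L, prob = vc)]
    }
  }
  list(k = k, l = l)
}

.distance_kl <- function(A, coords, v, side) {
  members <- .members(A, v, side)
  complement <- setdiff(seq_len(nrow(A)), c(v, members))
  d <- sqrt((coords[, 1] - coords[v, 1])^2 + (coords[, 2] - coords[v, 2])^2)
  dm <- d[members]
  dc <- d[complement]
  list(
    k = resample1(members[dm == max(dm)]),
    l = resample1(complement[dc == min(dc)])
  )
}

# cosine of each candidate edge to the field evaluated at the pivot;
# side "in": edges u -> v (head v), side "out": edges v -> u (head u).
# Coincident coordinates (zero-length edge) get a neutral cosine of 0.
.wave_cosines <- function(coords, v, u, side, f) {
  if (side == "in") {
    ex <- coords[v, 1] - coords[u, 1]
    ey <- coords[v, 2] - coords[u, 2]
  } else {
    ex <- coords[u, 1] - coords[v, 1]
    ey <- coords[u, 2] - coords[v, 2]
  }
  d <- sqrt(ex^2 + ey^2)
  cosv <- (ex * f[1] + ey * f[2]) / (d * sqrt(sum(f^2)))
  cosv[d == 0] <- 0
  cosv
}

.wave_kl <- function(A, coords, v, side, field) {
  f <- field_at(field, coords[v, ])
  if (is.null(f)) return(NULL) # radial field undefined at the origin
  members <- .members(A, v, side)
  complement <- setdiff(seq_len(nrow(A)), c(v, members))
  cm <- .wave_cosines(coords, v, members, side, f)
  cc <- .wave_cosines(coords, v, complement, side, f)
  list(
    k = resample1(members[cm == min(cm)]),
    l = resample1(complement[cc == max(cc)])
  )
}

.random_kl <- function(A, v, side) {
  members <- .members(A, v, side)
  complement <- setdiff(seq_len(nrow(A)), c(v, members))
  list(k = resample1(members), l = resample1(complement))
}

.swap_weight <- function(A, v, k, side) {
  if (side == "in") A[v, k] else A[k, v]
}

# ---- exported single-step operations --------------------------------------

#' Evaluate a rewiring vector field at a point
#'
#' `"lateral"` is the constant field (1, 0); `"radial"` is `x / ||x||`,
#' undefined at the origin (returns `NULL`, which [wave_rewire()] treats as
#' a fallback-to-random signal).
#'
#' @param kind `"lateral"` or `"radial"`.
#' @param point Numeric length-2 coordinates.
#' @return Length-2 field vector, or `NULL` where undefined.
#' @export
field_at <- function(kind = c("lateral", "radial"), point) {
  kind <- match.arg(kind)
  if (kind == "lateral") return(c(1, 0))
  nrm <- sqrt(sum(point^2))
  if (nrm == 0) return(NULL)
  point / nrm
}

#' Cosine between an edge and a field vector
#'
#' The cosine of the angle between the edge vector `head - tail` and
#' `field_vector`. Errors on zero-length edges or zero fields (the wave
#' principle applies its own fallback in those degenerate cases).
#'
#' @param head,tail Length-2 endpoint coordinates (edge tail -> head).
#' @param field_vector Length-2 non-zero vector.
#' @return Scalar in `[-1, 1]`.
#' @export
edge_field_cosine <- function(head, tail, field_vector) {
  e <- head - tail
  d <- sqrt(sum(e^2))
  fn <- sqrt(sum(field_vector^2))
  if (d == 0) stop("zero-length edge: angle undefined", call. = FALSE)
  if (fn == 0) stop("zero field vector: angle undefined", call. = FALSE)
  min(1, max(-1, sum(e * field_vector) / (d * fn)))
}

#' Functional (adaptive) rewiring step at a pivot
#'
#' Rewiring an in-link uses the pivot's consensus in-flow profile; an
#' out-link uses its advection out-flow profile. In deterministic mode the
#' member with the lowest kernel value is cut and the complement node with
#' the highest is added (ties uniform at random). In stochastic mode the
#' cut is drawn with probability proportional to 1/value and the addition
#' with probability proportional to the value; zero-valued members dominate
#' the cut draw and an all-zero complement falls back to a uniform choice.
#'
#' @param g A [spatial_digraph()].
#' @param v Pivot node (eligible per [select_pivot()]).
#' @param side `"in"` or `"out"`.
#' @param t Kernel interval.
#' @param mode `"deterministic"` or `"stochastic"`.
#' @return An `edge_swap` (pivot, side, removed, added, weight, principle).
#' @export
functional_rewire <- function(g, v, side = c("in", "out"), t = 1,
                              mode = c("deterministic", "stochastic")) {
  side <- match.arg(side)
  mode <- match.arg(mode)
  kl <- .functional_kl(g$adjacency, v, side, t, mode)
  .edge_swap(v, side, kl$k, kl$l, .swap_weight(g$adjacency, v, kl$k, side), "functional")
}

#' Distance-minimizing rewiring step at a pivot
#'
#' Cuts the member at maximal Euclidean distance from the pivot and adds
#' the complement node at minimal distance (ties uniform at random).
#'
#' @inheritParams functional_rewire
#' @return An `edge_swap`.
#' @export
distance_rewire <- function(g, v, side = c("in", "out")) {
  side <- match.arg(side)
  kl <- .distance_kl(g$adjacency, g$coordinates, v, side)
  .edge_swap(v, side, kl$k, kl$l, .swap_weight(g$adjacency, v, kl$k, side), "distance")
}

#' Wave (field-alignment) rewiring step at a pivot
#'
#' Evaluates the field at the pivot's coordinates, cuts the member whose
#' edge has the smallest cosine to the field (largest angle) and adds the
#' complement node with the largest cosine (ties uniform at random). If the
#' pivot sits exactly at the origin under the radial field — where the
#' field is undefined — the step falls back to uniform random rewiring and
#' the returned swap is tagged `"wave_random_fallback"`.
#'
#' @inheritParams functional_rewire
#' @param field `"lateral"` or `"radial"`.
#' @return An `edge_swap`.
#' @export
wave_rewire <- function(g, v, side = c("in", "out"), field = c("lateral", "radial")) {
  side <- match.arg(side)
  field <- match.arg(field)
  kl <- .wave_kl(g$adjacency, g$coordinates, v, side, field)
  if (is.null(kl)) {
    kl <- .random_kl(g$adjacency, v, side)
    return(.edge_swap(v, side, kl$k, kl$l, .swap_weight(g$adjacency, v, kl$k, side),
                      "wave_random_fallback"))
  }
  .edge_swap(v, side, kl$k, kl$l, .swap_weight(g$adjacency, v, kl$k, side), "wave")
}

#' Uniform random rewiring step at a pivot
#'
#' Cuts a uniform member and adds a uniform complement node.
#'
#' @inheritParams functional_rewire
#' @return An `edge_swap`.
#' @export
random_rewire <- function(g, v, side = c("in", "out")) {
  side <- match.arg(side)
  kl <- .random_kl(g$adjacency, v, side)
  .edge_swap(v, side, kl$k, kl$l, .swap_weight(g$adjacency, v, kl$k, side), "random")
}

#' Apply an edge swap to a digraph
#'
#' Moves the removed edge's weight onto the added edge: for an in-side swap
#' at pivot `v`, edge `(k, v)` is zeroed and `(l, v)` receives its weight,
#' so the number and total strength of `v`'s in-links are unchanged (and
#' symmetrically for out-side swaps). Errors if the swap is inconsistent
#' with the graph (removed edge absent, added edge present, or self-loop).
#'
#' @param g A [spatial_digraph()].
#' @param swap An `edge_swap`.
#' @return The updated `spatial_digraph`.
#' @export
apply_swap <- function(g, swap) {
  A <- g$adjacency
  v <- swap$pivot; k <- swap$removed; l <- swap$added
  if (k == l || l == v || k == v) stop("inconsistent swap: degenerate node indices", call. = FALSE)
  if (swap$side == "in") {
    if (A[v, k] <= 0) stop("inconsistent swap: removed in-link absent", call. = FALSE)
    if (A[v, l] != 0) stop("inconsistent swap: added in-link already present", call. = FALSE)
    A[v, l] <- A[v, k]
    A[v, k] <- 0
  } else {
    if (A[k, v] <= 0) stop("inconsistent swap: removed out-link absent", call. = FALSE)
    if (A[l, v] != 0) stop("inconsistent swap: added out-link already present", call. = FALSE)
    A[l, v] <- A[k, v]
    A[k, v] <- 0
  }
  g$adjacency <- A
  g
}

# internal fast per-step CDU-existence flag: TRUE when at least one
# convergent hub reaches at least one divergent hub (binary BFS on the
# adjacency pattern, A[i, j] > 0 meaning edge j -> i).
.cdu_present_fast <- function(A, threshold) {
  P <- A > 0
  indeg <- rowSums(P)
  outdeg <- colSums(P)
  conv <- which(indeg > threshold & outdeg >= 1)
  divg <- which(outdeg > threshold & indeg >= 1)
  if (length(conv) == 0L || length(divg) == 0L) return(FALSE)
  for (c_hub in conv) {
    reached <- logical(nrow(A))
    frontier <- c_hub
    repeat {
      # out-neighbors of the frontier: rows with an entry in those columns
      nxt <- which(rowSums(P[, frontier, drop = FALSE]) > 0 & !reached)
      if (length(nxt) == 0L) break
      if (any(nxt %in% divg)) return(TRUE)
      reached[nxt] <- TRUE
      frontier <- nxt
    }
    if (any(reached[divg])) return(TRUE)
  }
  FALSE
}

#' Run a full rewiring trajectory
#'
#' Executes `config$steps` rewiring steps from `g0`, recording the metric
#' suite at a checkpoint cadence and (optionally) a cheap
#' convergent-divergent-unit existence flag at a finer cadence. The run is
#' fully reproducible from `(g0, config)`: the RNG stream is seeded from
#' `config$seed` and restored afterwards.
#'
#' @param g0 Initial [spatial_digraph()].
#' @param config A [rewiring_config()].
#' @param checkpoint_every Steps between metric checkpoints (0 disables
#'   intermediate checkpoints; step 0 and the final step are always
#'   recorded when `metrics = TRUE`).
#' @param cdu_every Steps between CDU-existence flags (0 disables).
#' @param hub_threshold Degree threshold for hub detection.
#' @param metrics Logical: record metric checkpoints?
#' @param metrics_include Character vector of metric groups, see
#'   [compute_metrics()].
#' @param keep_graphs Logical: retain a snapshot of the graph at every
#'   metric checkpoint (memory-heavy; default keeps only initial/final).
#' @param on_step Optional callback `function(step, g_before, swap, g_after)`
#'   invoked after every applied swap (for auditing/conservation checks).
#' @return A `rewiring_trajectory`: list with `initial`, `final`, `config`,
#'   `metrics` (data frame, one row per checkpoint), `cdu_flags` (data frame
#'   step/cdu_present), `swap_log` (data frame, one row per step) and
#'   optionally `snapshots`.
#' @export
run_rewiring <- function(g0, config, checkpoint_every = 100L, cdu_every = 0L,
                         hub_threshold = 15L, metrics = TRUE,
                         metrics_include = c("connectivity", "hubs", "cdu",
                                             "modularity", "spatial"),
                         keep_graphs = FALSE, on_step = NULL) {
  validate_spatial_digraph(g0)
  stopifnot(inherits(config, "rewiring_config"))
  M <- config$steps
  n <- g0$n
  A <- g0$adjacency
  coords <- g0$coordinates

  step_v <- integer(M); side_v <- character(M); principle_v <- character(M)
  removed_v <- integer(M); added_v <- integer(M); weight_v <- numeric(M)
  pivot_v <- integer(M)
  cdu_steps <- integer(0); cdu_flags <- logical(0)
  metric_rows <- list()
  snapshots <- if (keep_graphs) list() else NULL

  snap <- function() spatial_digraph(A, coords)
  record_metrics <- function(step) {
    g <- snap()
    row <- compute_metrics(g, hub_threshold = hub_threshold,
                           field = config$field, include = metrics_include)
    row$step <- step
    metric_rows[[length(metric_rows) + 1L]] <<- row
    if (keep_graphs) snapshots[[as.character(step)]] <<- g
  }

  with_seed(config$seed, {
    if (metrics) record_metrics(0L)
    if (cdu_every > 0L) {
      cdu_steps <- c(cdu_steps, 0L)
      cdu_flags <- c(cdu_flags, .cdu_present_fast(A, hub_threshold))
    }
    step <- 0L
    while (step < M) {
      step <- step + 1L
      side <- if (runif(1) < config$p_in) "in" else "out"
      deg <- if (side == "in") rowSums(A > 0) else colSums(A > 0)
      eligible <- which(deg >= 1 & deg <= n - 2L)
      if (length(eligible) == 0L) {
        stop(sprintf("step %d: no node with %s-degree in {1, ..., n-2}", step, side),
             call. = FALSE)
      }
      v <- resample1(eligible)
      principle <- .principle_from_r2(runif(1), config)
      kl <- switch(principle,
        functional = .functional_kl(A, v, side, config$t, config$mode),
        distance = .distance_kl(A, coords, v, side),
        wave = .wave_kl(A, coords, v, side, config$field),
        random = .random_kl(A, v, side)
      )
      if (is.null(kl)) { # radial field undefined at the pivot: random fallback
        kl <- .random_kl(A, v, side)
        principle <- "wave_random_fallback"
      }
      k <- kl$k; l <- kl$l
      w <- if (side == "in") A[v, k] else A[k, v]
      A_before <- if (!is.null(on_step)) A else NULL
      if (side == "in") {
        A[v, l] <- w; A[v, k] <- 0
      } else {
        A[l, v] <- w; A[k, v] <- 0
      }
      pivot_v[step] <- v; side_v[step] <- side; principle_v[step] <- principle
      removed_v[step] <- k; added_v[step] <- l; weight_v[step] <- w
      step_v[step] <- step
      if (!is.null(on_step)) {
        on_step(step, spatial_digraph(A_before, coords),
                .edge_swap(v, side, k, l, w, principle),
                spatial_digraph(A, coords))
      }
      if (cdu_every > 0L && step %% cdu_every == 0L) {
        cdu_steps <- c(cdu_steps, step)
        cdu_flags <- c(cdu_flags, .cdu_present_fast(A, hub_threshold))
      }
      if (metrics &&
          ((checkpoint_every > 0L && step %% checkpoint_every == 0L) || step == M)) {
        record_metrics(step)
      }
    }
  })

  metrics_df <- if (length(metric_rows)) do.call(rbind, metric_rows) else NULL
  if (!is.null(metrics_df)) {
    # drop duplicate final checkpoint if M is a multiple of the cadence
    metrics_df <- metrics_df[!duplicated(metrics_df$step), , drop = FALSE]
    metrics_df <- metrics_df[order(metrics_df$step), , drop = FALSE]
    rownames(metrics_df) <- NULL
    metrics_df <- metrics_df[, c("step", setdiff(names(metrics_df), "step")), drop = FALSE]
  }
  structure(
    list(
      initial = g0,
      final = spatial_digraph(A, coords),
      config = config,
      metrics = metrics_df,
      cdu_flags = if (length(cdu_steps)) {
        data.frame(step = cdu_steps, cdu_present = cdu_flags)
      } else NULL,
      swap_log = data.frame(
        step = step_v, pivot = pivot_v, side = side_v, principle = principle_v,
        removed = removed_v, added = added_v, weight = weight_v,
        stringsAsFactors = FALSE
      ),
      snapshots = snapshots
    ),
    class = "rewiring_trajectory"
  )
}

#' @export
print.rewiring_trajectory <- function(x, ...) {
  cat(sprintf(
    "<rewiring_trajectory>  %d steps on n = %d, m = %d (seed %d)\n",
    x$config$steps, x$initial$n, x$initial$m, x$config$seed
  ))
  if (!is.null(x$metrics)) {
    cat(sprintf("  %d metric checkpoints recorded\n", nrow(x$metrics)))
  }
  invisible(x)
}
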