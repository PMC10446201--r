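# Experiment runner: seeded multi-instantiation conditions, sweeps over
# principle probabilities, stabilization analysis, and shared fixtures.

#' Run one experimental condition over several instantiations
#'
#' Executes `runs` independent trajectories with seeds `base_seed + 0, ...,
#' base_seed + runs - 1`. Each instantiation generates a fresh random
#' initial digraph (same `n`, `m`, weight distribution) and rewires it for
#' `steps` steps. Final-checkpoint metrics are aggregated as mean and
#' standard deviation over runs.
#'
#' @param params Named list of [rewiring_config()] arguments (except
#'   `steps` and `seed`), e.g. `list(p_in = 0.5, p_function = 0.5)`.
#' @param runs Number of instantiations (default 3; the full-scale protocol
#'   uses 10).
#' @param steps Rewiring steps per run (default 3000; full scale 15000).
#' @param base_seed First seed.
#' @param n,m Node and edge counts of the generated initial digraphs.
#' @param weights A [weight_spec()].
#' @param checkpoint_every,cdu_every,hub_threshold,metrics_include,keep_graphs
#'   Passed to [run_rewiring()].
#' @return A `condition_summary`: list with `params`, `summary` (data frame
#'   metric/mean/sd/n_runs), `finals` (per-run final metrics, including
#'   `no_cdu_step_proportion` when `cdu_every > 0`), `series` (all
#'   checkpoints, with a `run` column), `seeds`, and `final_graphs` when
#'   `keep_graphs = TRUE`.
#' @export
run_condition <- function(params, runs = 3L, steps = 3000L, base_seed = 1L,
                          n = 100L, m = 912L, weights = weight_spec(),
                          checkpoint_every = 100L, cdu_every = 0L,
                          hub_threshold = 15L,
                          metrics_include = c("connectivity", "hubs", "cdu",
                                              "modularity", "spatial"),
                          keep_graphs = FALSE) {
  if (runs < 1) stop("runs must be >= 1", call. = FALSE)
  seeds <- base_seed + seq_len(runs) - 1L
  finals <- list()
  series <- list()
  final_graphs <- if (keep_graphs) list() else NULL
  for (k in seq_len(runs)) {
    config <- do.call(rewiring_config, c(params, list(steps = steps, seed = seeds[k])))
    g0 <- with_seed(seeds[k], generate_random_digraph(n, m, weights))
    traj <- run_rewiring(g0, config,
      checkpoint_every = checkpoint_every, cdu_every = cdu_every,
      hub_threshold = hub_threshold, metrics_include = metrics_include
    )
    fin <- traj$metrics[nrow(traj$metrics), , drop = FALSE]
    fin$run <- k
    fin$seed <- seeds[k]
    if (!is.null(traj$cdu_flags)) {
      fin$no_cdu_step_proportion <- mean(!traj$cdu_flags$cdu_present)
    }
    finals[[k]] <- fin
    ser <- traj$metrics
    ser$run <- k
    series[[k]] <- ser
    if (keep_graphs) final_graphs[[k]] <- traj$final
  }
  finals <- do.call(rbind, finals)
  num_cols <- setdiff(
    names(finals)[vapply(finals, is.numeric, logical(1))],
    c("step", "run", "seed")
  )
  nan2na <- function(x) { x[is.nan(x)] <- NA_real_; x }
  summary <- data.frame(
    metric = num_cols,
    mean = nan2na(vapply(num_cols, function(cl) mean(finals[[cl]], na.rm = TRUE), numeric(1))),
    sd = if (runs > 1) {
      vapply(num_cols, function(cl) sd(finals[[cl]], na.rm = TRUE), numeric(1))
    } else {
      rep(0, length(num_cols))
    },
    n_runs = vapply(num_cols, function(cl) sum(!is.na(finals[[cl]])), numeric(1)),
    row.names = NULL
  )
  structure(
    list(
      params = params, runs = runs, steps = steps, seeds = seeds,
      summary = summary, finals = finals, series = do.call(rbind, series),
      final_graphs = final_graphs
    ),
    class = "condition_summary"
  )
}

#' @export
print.condition_summary <- function(x, ...) {
  cat(sprintf("<condition_summary>  %d runs x %d steps\n", x$runs, x$steps))
  print(x$summary, digits = 4)
  invisible(x)
}

#' Sweep a grid of rewiring conditions
#'
#' Runs [run_condition()] for every row of `grid` (columns are
#' [rewiring_config()] arguments such as `p_in`, `p_function`,
#' `p_distance`, `p_wave`, `mode`, `field`) and assembles a long-format
#' results table: one row per condition and metric, with mean and sd over
#' instantiations. Seeds are spaced so conditions use disjoint seed blocks.
#'
#' @param grid Data frame of condition parameters (e.g. from `expand.grid`).
#' @param out_csv Optional path: write the long table as CSV.
#' @inheritParams run_condition
#' @return List with `results` (long data frame) and `conditions` (list of
#'   `condition_summary`).
#' @export
run_sweep <- function(grid, runs = 3L, steps = 3000L, base_seed = 1L,
                      n = 100L, m = 912L, weights = weight_spec(),
                      checkpoint_every = 100L, cdu_every = 0L,
                      hub_threshold = 15L,
                      metrics_include = c("connectivity", "hubs", "cdu",
                                          "modularity", "spatial"),
                      out_csv = NULL) {
  grid <- as.data.frame(grid, stringsAsFactors = FALSE)
  conditions <- vector("list", nrow(grid))
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    params <- as.list(grid[i, , drop = FALSE])
    params <- lapply(params, function(x) if (is.factor(x)) as.character(x) else x)
    cs <- run_condition(params,
      runs = runs, steps = steps,
      base_seed = base_seed + (i - 1L) * 1000L, n = n, m = m, weights = weights,
      checkpoint_every = checkpoint_every, cdu_every = cdu_every,
      hub_threshold = hub_threshold, metrics_include = metrics_include
    )
    conditions[[i]] <- cs
    rows[[i]] <- cbind(grid[i, , drop = FALSE], cs$summary, row.names = NULL)
  }
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  if (!is.null(out_csv)) write.csv(results, out_csv, row.names = FALSE)
  list(results = results, conditions = conditions)
}

#' First checkpoint at which a metric series stabilizes
#'
#' The terminal mean is the mean of the last 10% of checkpoints (at least
#' one). The series is declared stable from the first checkpoint onwards
#' such that every value from there to the end stays within
#' `tolerance * |terminal mean|` of the terminal mean. Returns the step of
#' that checkpoint, or the final step when the series never settles.
#'
#' @param steps Checkpoint step indices (increasing).
#' @param values Metric values at those checkpoints (same length, >= 3).
#' @param tolerance Relative band half-width (default 0.1).
#' @return A step index from `steps`.
#' @export
stabilization_step <- function(steps, values, tolerance = 0.1) {
  len <- length(values)
  if (len != length(steps)) stop("steps and values must have equal length", call. = FALSE)
  if (len < 3) stop("series must have at least 3 checkpoints", call. = FALSE)
  terminal <- mean(tail(values, max(1L, ceiling(0.1 * len))))
  within <- abs(values - terminal) <= tolerance * abs(terminal)
  suffix_ok <- rev(cumprod(rev(within))) > 0
  idx <- which(suffix_ok)
  if (length(idx) == 0L) steps[len] else steps[idx[1]]
}

#' Deterministic fixture digraphs
#'
#' Small graphs used throughout the examples and tests:
#' \describe{
#'   \item{two-node-single-edge}{2 nodes, one edge `2 -> 1`, weight 1.}
#'   \item{three-cycle}{Directed 3-cycle `1 -> 2 -> 3 -> 1`, weights 1.}
#'   \item{complete-4}{Complete loopless digraph on 4 nodes (12 edges).}
#'   \item{two-cliques}{Two disconnected complete loopless digraphs on 5
#'     nodes each (uniform weights); the known two-block partition has
#'     directed modularity 0.5.}
#'   \item{cdu-minimal}{35 nodes: 16 sources feeding a convergent hub,
#'     one intermediate node, a divergent hub broadcasting to 16 targets —
#'     exactly one convergent-divergent unit at threshold 15.}
#' }
#'
#' @param name Fixture tag.
#' @return A [spatial_digraph()].
#' @export
make_fixture <- function(name = c("two-node-single-edge", "three-cycle",
                                  "complete-4", "two-cliques", "cdu-minimal")) {
  name <- match.arg(name)
  circle <- function(n, r = 0.8) {
    th <- 2 * pi * (seq_len(n) - 1) / n
    cbind(r * cos(th), r * sin(th))
  }
  switch(name,
    "two-node-single-edge" = {
      A <- matrix(0, 2, 2)
      A[1, 2] <- 1 # edge 2 -> 1
      spatial_digraph(A, rbind(c(-0.5, 0), c(0.5, 0)))
    },
    "three-cycle" = {
      A <- matrix(0, 3, 3)
      A[2, 1] <- 1; A[3, 2] <- 1; A[1, 3] <- 1
      spatial_digraph(A, circle(3))
    },
    "complete-4" = {
      A <- matrix(1, 4, 4)
      diag(A) <- 0
      spatial_digraph(A, circle(4))
    },
    "two-cliques" = {
      A <- matrix(0, 10, 10)
      A[1:5, 1:5] <- 1
      A[6:10, 6:10] <- 1
      diag(A) <- 0
      left <- circle(5, 0.4); left[, 1] <- left[, 1] - 0.55
      right <- circle(5, 0.4); right[, 1] <- right[, 1] + 0.55
      spatial_digraph(A, rbind(left, right))
    },
    "cdu-minimal" = {
      n <- 35L
      A <- matrix(0, n, n)
      A[17, 1:16] <- 1  # sources 1..16 -> convergent hub 17
      A[18, 17] <- 1    # hub -> intermediate node 18
      A[19, 18] <- 1    # intermediate -> divergent hub 19
      A[20:35, 19] <- 1 # divergent hub -> targets 20..35
      xy <- rbind(
        circle(16, 0.9),
        c(-0.3, 0), c(0, 0.1), c(0.3, 0),
        circle(16, 0.6)
      )
      spatial_digraph(A, xy)
    }
  )
}

#' Line panels of swept metrics
#'
#' Plots condition means with a +/- sd ribbon against a swept probability,
#' one line per grouping value — the standard way of reading a sweep.
#' Requires ggplot2.
#'
#' @param results Long results table from [run_sweep()].
#' @param metric Metric name to plot.
#' @param x Name of the swept probability column.
#' @param group Optional name of a grouping column (e.g. `"p_in"`).
#' @return A ggplot object.
#' @export
plot_metric_panels <- function(results, metric, x, group = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  df <- results[results$metric == metric, , drop = FALSE]
  if (nrow(df) == 0) stop(sprintf("metric '%s' not present in results", metric), call. = FALSE)
  df$.x <- df[[x]]
  df$.ymin <- df$mean - df$sd
  df$.ymax <- df$mean + df$sd
  df$.group <- if (is.null(group)) factor(1) else factor(df[[group]])
  mapping <- ggplot2::aes(x = .x, y = mean, colour = .group, fill = .group, group = .group)
  p <- ggplot2::ggplot(df, mapping) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .ymin, ymax = .ymax),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = x, y = metric, colour = group, fill = group) +
    ggplot2::theme_minimal()
  if (is.null(group)) p <- p + ggplot2::guides(colour = "none", fill = "none")
  p
}

#' Spatial layout snapshot of a digraph
#'
#' Draws nodes at their disk coordinates and edges as arrows from tail to
#' head. Requires ggplot2.
#'
#' @param g A [spatial_digraph()].
#' @return A ggplot object.
#' @export
plot_network_layout <- function(g) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  xy <- g$coordinates
  nodes <- data.frame(x = xy[, 1], y = xy[, 2])
  edges <- which(g$adjacency > 0, arr.ind = TRUE)
  seg <- data.frame(
    x = xy[edges[, 2], 1], y = xy[edges[, 2], 2],
    xend = xy[edges[, 1], 1], yend = xy[edges[, 1], 2]
  )
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = x, y = y, xend = xend, yend = yend),
      arrow = grid::arrow(length = grid::unit(0.12, "cm")),
      alpha = 0.4, linewidth = 0.3
    ) +
    ggplot2::geom_point(data = nodes, ggplot2::aes(x = x, y = y), size = 1) +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
}
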