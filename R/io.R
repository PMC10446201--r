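# Import/export. The package stores A[i, j] = weight of edge j -> i;
# igraph and the on-disk formats use the from -> to convention, so every
# boundary crossing transposes.

#' Convert a spatial digraph to an igraph object
#'
#' Edge direction follows igraph's from -> to convention; node coordinates
#' are attached as vertex attributes `x` and `y`, weights as the edge
#' attribute `weight`.
#'
#' @param g A [spatial_digraph()].
#' @return A directed, weighted `igraph` graph.
#' @export
as_igraph <- function(g) {
  ig <- igraph::graph_from_adjacency_matrix(t(g$adjacency), mode = "directed",
                                            weighted = TRUE)
  igraph::V(ig)$x <- g$coordinates[, 1]
  igraph::V(ig)$y <- g$coordinates[, 2]
  ig
}

#' Convert an igraph object to a spatial digraph
#'
#' Requires vertex attributes `x` and `y` (coordinates in the unit disk);
#' missing edge weights default to 1.
#'
#' @param ig A directed `igraph` graph.
#' @return A [spatial_digraph()].
#' @export
from_igraph <- function(ig) {
  if (!igraph::is_directed(ig)) stop("graph must be directed", call. = FALSE)
  At <- as.matrix(igraph::as_adjacency_matrix(
    ig, attr = if ("weight" %in% igraph::edge_attr_names(ig)) "weight" else NULL,
    sparse = TRUE
  ))
  va <- igraph::vertex_attr_names(ig)
  if (!all(c("x", "y") %in% va)) stop("vertex attributes x and y are required", call. = FALSE)
  spatial_digraph(t(At), cbind(igraph::V(ig)$x, igraph::V(ig)$y))
}

#' Write a digraph as a weighted edge list (TSV)
#'
#' Columns `source`, `target`, `weight`, one edge per line, 0-based node
#' indices, weights at full precision (17 significant digits: the round
#' trip is bit-exact). Coordinates are not stored in this format; use
#' [write_graphml()] to keep the embedding (at ~15 significant digits,
#' the precision of igraph's GraphML writer).
#'
#' @param g A [spatial_digraph()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(g, path) {
  edges <- which(g$adjacency > 0, arr.ind = TRUE) # [, 1] head, [, 2] tail
  df <- data.frame(
    source = edges[, 2] - 1L,
    target = edges[, 1] - 1L,
    weight = sprintf("%.17g", g$adjacency[edges])
  )
  df <- df[order(df$source, df$target), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a weighted edge list (TSV)
#'
#' @param path File written by [write_edge_list()] (0-based indices).
#' @param n Node count; defaults to the largest index + 1 (isolated
#'   trailing nodes then need an explicit `n`).
#' @param coordinates Optional `n x 2` coordinate matrix; defaults to the
#'   origin for every node.
#' @return A [spatial_digraph()].
#' @export
read_edge_list <- function(path, n = NULL, coordinates = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c("integer", "integer", "numeric"))
  if (is.null(n)) n <- max(df$source, df$target) + 1L
  A <- matrix(0, n, n)
  A[cbind(df$target + 1L, df$source + 1L)] <- df$weight
  if (is.null(coordinates)) coordinates <- matrix(0, n, 2)
  spatial_digraph(A, coordinates)
}

#' Write a digraph as GraphML
#'
#' Stores node coordinates as attributes `x`/`y` and weights as `weight`.
#'
#' @param g A [spatial_digraph()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(g, path) {
  igraph::write_graph(as_igraph(g), path, format = "graphml")
  invisible(path)
}

#' Read a digraph from GraphML
#'
#' @param path File with `x`/`y` node attributes and `weight` edge attribute.
#' @return A [spatial_digraph()].
#' @export
read_graphml <- function(path) {
  from_igraph(igraph::read_graph(path, format = "graphml"))
}

#' Write convergent-divergent units as JSON lines
#'
#' One JSON object per unit with the hub pair, node sets (1-based indices)
#' and intermediate-subgraph statistics.
#'
#' @param units List from [find_cdus()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cdu_jsonl <- function(units, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (u in units) {
    writeLines(jsonlite::toJSON(list(
      convergent_hub = u$convergent_hub,
      divergent_hub = u$divergent_hub,
      source_nodes = u$source_nodes,
      target_nodes = u$target_nodes,
      intermediate_nodes = u$intermediate_nodes,
      intermediate_size_proportion = u$intermediate_size_proportion,
      intermediate_density = u$intermediate_density
    ), auto_unbox = TRUE, digits = NA, null = "null"), con)
  }
  invisible(path)
}
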