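#' Time-aggregated contact graph
#'
#' Collapses an event stream over all times into a simple undirected graph:
#' one vertex per registry entry (silent and self-contact-only vertices become
#' isolates) and one edge per distinct contacted pair, however many events or
#' directions connect it.
#'
#' @inheritParams event_vertices
#' @return An [igraph::igraph] object.
#' @export
aggregate_graph <- function(stream) {
  stopifnot(inherits(stream, "event_stream"))
  vertices <- event_vertices(stream)
  pairs <- stream[!is.na(stream$j), c("i", "j"), drop = FALSE]
  if (nrow(pairs) > 0) {
    a <- pmin(pairs$i, pairs$j)
    b <- pmax(pairs$i, pairs$j)
    keep <- !duplicated(paste(a, b, sep = "\r"))
    edges <- data.frame(from = a[keep], to = b[keep])
  } else {
    edges <- data.frame(from = character(), to = character())
  }
  igraph::graph_from_data_frame(edges, directed = FALSE,
                                vertices = data.frame(name = vertices))
}

#' Static graph features of a contact dataset
#'
#' The conventional social-network-analysis baseline on the time-aggregated
#' graph: vertex and edge counts, diameter and mean shortest-path distance
#' (`Inf` when some vertices are never connected), graph density, mean local
#' clustering coefficient (vertices of degree < 2 contribute 0), and the
#' temporal record counts `t_count` / `t_max`.
#'
#' Two edge notions are reported: `edge_count` is the number of distinct
#' undirected pairs (the notion entering the density), while
#' `event_edge_count` is the raw number of event records including repeats.
#'
#' @inheritParams event_vertices
#' @return A one-row `graph_features` tibble.
#' @export
graph_features <- function(stream) {
  stopifnot(inherits(stream, "event_stream"))
  g <- aggregate_graph(stream)
  v <- igraph::vcount(g)
  if (v < 2) abort("graph density is undefined for fewer than 2 vertices")
  e <- igraph::ecount(g)
  connected <- igraph::is_connected(g)
  diameter <- if (connected) as.numeric(igraph::diameter(g)) else Inf
  mean_distance <- if (connected) igraph::mean_distance(g) else Inf
  local_cc <- igraph::transitivity(g, type = "localundirected",
                                   isolates = "zero")
  out <- tibble(
    vertex_count = v,
    edge_count = e,
    event_edge_count = nrow(stream),
    diameter = diameter,
    mean_distance = mean_distance,
    density = 2 * e / (v * (v - 1)),
    mean_clustering = mean(local_cc),
    t_count = t_count(stream),
    t_max = t_max(stream)
  )
  new_tibble(out, class = "graph_features", nrow = 1L)
}

#' @rdname graph_features
#' @param x A `graph_features` row.
#' @param ... Unused.
#' @export
glance.graph_features <- function(x, ...) as_tibble(x)
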