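#' Spatial skeleton graph container
#'
#' A light container for a spatially embedded network: a node table with
#' 3D positions (um), an edge table with geodesic path lengths and chord
#' vectors, and the corresponding [igraph::graph()] for topology queries.
#'
#' @param nodes Data frame with columns `id`, `x_um`, `y_um`, `z_um`.
#' @param edges Data frame with columns `from`, `to`, `path_length_um`
#'   (chord components are filled in if absent).
#' @param major_axis Unit 3-vector of the cell's major axis.
#' @return A `skeleton_graph` list with elements `nodes`, `edges`,
#'   `graph`, `major_axis`.
#' @export
skeleton_graph <- function(nodes, edges, major_axis = c(1, 0, 0)) {
  stopifnot(all(c("id", "x_um", "y_um", "z_um") %in% names(nodes)))
  nodes$id <- as.integer(nodes$id)
  if (nrow(edges) > 0) {
    stopifnot(all(c("from", "to") %in% names(edges)))
    pos <- as.matrix(nodes[c("x_um", "y_um", "z_um")])
    rownames(pos) <- nodes$id
    a <- pos[as.character(edges$from), , drop = FALSE]
    b <- pos[as.character(edges$to), , drop = FALSE]
    chord <- b - a
    edges$chord_x <- chord[, 1]; edges$chord_y <- chord[, 2]
    edges$chord_z <- chord[, 3]
    clen <- sqrt(rowSums(chord^2))
    if (is.null(edges$path_length_um)) edges$path_length_um <- clen
    edges$path_length_um <- pmax(edges$path_length_um, clen)
  } else {
    edges <- data.frame(from = integer(0), to = integer(0),
                        path_length_um = numeric(0), chord_x = numeric(0),
                        chord_y = numeric(0), chord_z = numeric(0))
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(edges$from), to = as.character(edges$to)),
    directed = FALSE,
    vertices = data.frame(name = as.character(nodes$id)))
  structure(list(nodes = nodes, edges = edges, graph = g,
                 major_axis = major_axis / sqrt(sum(major_axis^2))),
            class = "skeleton_graph")
}

#' First Betti number (cycle rank) of a skeleton graph
#'
#' `beta1 = E - N + C`: the number of independent cycles; the network's
#' topological genus is `beta1 / 2`.
#'
#' @param graph A [skeleton_graph()] or an igraph object.
#' @return Non-negative integer.
#' @export
graph_beta1 <- function(graph) {
  g <- if (inherits(graph, "skeleton_graph")) graph$graph else graph
  igraph::ecount(g) - igraph::vcount(g) + igraph::count_components(g)
}

#' @export
print.skeleton_graph <- function(x, ...) {
  cat(sprintf(
    "skeleton_graph: %d nodes, %d edges, %d component(s), beta1 = %d (genus %.1f)\n",
    nrow(x$nodes), nrow(x$edges), igraph::count_components(x$graph),
    graph_beta1(x), graph_beta1(x) / 2))
  invisible(x)
}

node_positions <- function(graph) {
  as.matrix(graph$nodes[c("x_um", "y_um", "z_um")])
}

#' Export or import a skeleton graph as CSV tables
#'
#' Writes `<stem>_nodes.csv` (`id, x_um, y_um, z_um`) and
#' `<stem>_edges.csv` (`from, to, path_length_um, chord_*`).
#'
#' @param graph A [skeleton_graph()].
#' @param stem Output path stem.
#' @export
write_graph_csv <- function(graph, stem) {
  utils::write.csv(graph$nodes, paste0(stem, "_nodes.csv"), row.names = FALSE)
  utils::write.csv(graph$edges, paste0(stem, "_edges.csv"), row.names = FALSE)
  invisible(stem)
}

#' @rdname write_graph_csv
#' @export
read_graph_csv <- function(stem) {
  skeleton_graph(utils::read.csv(paste0(stem, "_nodes.csv")),
                 utils::read.csv(paste0(stem, "_edges.csv")))
}
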