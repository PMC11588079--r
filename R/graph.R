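#' Extract a spatial graph from a labeled or binary volume
#'
#' Skeletonizes the union of foreground labels ([skeletonize3d()]),
#' classifies skeleton voxels by their 26-neighbor count (1 = endpoint,
#' >= 3 = junction), clusters touching junction/end voxels into single
#' nodes at their centroid, and traces the degree-2 skeleton paths
#' between nodes into edges carrying the geodesic path length (sum of
#' anisotropic voxel steps, um) and the straight chord. A closed skeleton
#' loop without any junction becomes a single node with a self-loop edge,
#' preserving its cycle in `beta1`.
#'
#' @param labeled A `labeled_volume` from [segment_volume()], or a logical
#'   array/matrix.
#' @param voxel_size_um Named voxel size `c(x=, y=, z=)` (um).
#' @param major_axis Unit 3-vector for orientation metrics (default x).
#' @return A [skeleton_graph()]; empty (with a warning) when the mask
#'   thins to nothing.
#' @export
skeletonize_to_graph <- function(labeled, voxel_size_um = c(x = 1, y = 1, z = 1),
                                 major_axis = c(1, 0, 0)) {
  mask <- if (inherits(labeled, "labeled_volume")) labeled$labels > 0L else labeled
  if (is.matrix(mask)) mask <- array(mask, dim = c(dim(mask), 1L))
  vs <- c(voxel_size_um[["x"]], voxel_size_um[["y"]], voxel_size_um[["z"]])
  empty <- function() {
    warning("mask produced an empty skeleton", call. = FALSE)
    skeleton_graph(data.frame(id = integer(0), x_um = numeric(0),
                              y_um = numeric(0), z_um = numeric(0)),
                   data.frame(from = integer(0), to = integer(0)),
                   major_axis = major_axis)
  }
  if (!any(mask)) return(empty())
  sk <- skeletonize3d(mask)
  vox <- which(sk, arr.ind = TRUE)
  m <- nrow(vox)
  if (m == 0L) return(empty())

  # adjacency among skeleton voxels (26-connectivity) with physical steps
  key <- function(ixyz) (ixyz[, 3] - 1) * (dim(sk)[1] * dim(sk)[2]) +
    (ixyz[, 2] - 1) * dim(sk)[1] + ixyz[, 1]
  id_of <- integer(prod(dim(sk)))
  id_of[key(vox)] <- seq_len(m)
  adj <- vector("list", m)
  step_len <- vector("list", m)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  d <- dim(sk)
  for (i in seq_len(nrow(offs))) {
    o <- offs[i, ]
    nb <- sweep(vox, 2, o, "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    tgt <- integer(m)
    tgt[ok] <- id_of[key(nb[ok, , drop = FALSE])]
    hit <- which(tgt > 0L)
    len <- sqrt(sum((o * vs)^2))
    for (v in hit) {
      adj[[v]] <- c(adj[[v]], tgt[v])
      step_len[[v]] <- c(step_len[[v]], len)
    }
  }
  deg <- lengths(adj)
  pos_um <- sweep(vox - 1, 2, vs, "*")

  is_node <- deg != 2L
  # pure cycles: components with all degree 2 get one seed node
  if (!all(is_node)) {
    gg <- igraph::graph_from_edgelist(
      do.call(rbind, lapply(which(deg > 0), function(v)
        cbind(v, adj[[v]]))), directed = FALSE)
    gg <- igraph::add_vertices(gg, max(0L, m - igraph::vcount(gg)))
    comp <- igraph::components(gg)$membership
    for (cid in unique(comp)) {
      members <- which(comp == cid)
      if (!any(is_node[members])) is_node[members[1]] <- TRUE
    }
  }
  if (!any(is_node)) is_node[1] <- TRUE

  # cluster touching node voxels into supernodes
  cluster <- integer(m)
  ncl <- 0L
  for (v in which(is_node)) {
    if (cluster[v] != 0L) next
    ncl <- ncl + 1L
    stack <- v
    while (length(stack)) {
      u <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (cluster[u] != 0L) next
      cluster[u] <- ncl
      nb <- adj[[u]]
      stack <- c(stack, nb[is_node[nb] & cluster[nb] == 0L])
    }
  }
  cl_pos <- t(vapply(seq_len(ncl), function(k)
    colMeans(pos_um[cluster == k, , drop = FALSE]), numeric(3)))

  # trace paths: direct node-node contacts and degree-2 chains
  edges <- list()
  add_edge <- function(a, b, len) edges[[length(edges) + 1L]] <<-
    c(a, b, len)
  seen_pair <- new.env(hash = TRUE)
  visited <- logical(m)
  for (v in which(is_node)) {
    nbs <- adj[[v]]; lens <- step_len[[v]]
    for (j in seq_along(nbs)) {
      u <- nbs[j]
      if (is_node[u]) {
        if (cluster[u] != cluster[v]) {
          k <- paste(min(cluster[u], cluster[v]), max(cluster[u], cluster[v]))
          if (is.null(seen_pair[[k]])) {
            seen_pair[[k]] <- TRUE
            add_edge(cluster[v], cluster[u], lens[j])
          }
        }
      } else if (!visited[u]) {
        plen <- lens[j]
        prev <- v; cur <- u
        repeat {
          visited[cur] <- TRUE
          nb2 <- adj[[cur]]
          nxt <- nb2[nb2 != prev]
          if (length(nxt) == 0L) { add_edge(cluster[v], NA, plen); break }
          nxt <- nxt[1]
          plen <- plen + step_len[[cur]][which(nb2 == nxt)[1]]
          if (is_node[nxt]) { add_edge(cluster[v], cluster[nxt], plen); break }
          prev <- cur; cur <- nxt
        }
      }
    }
  }
  edges <- do.call(rbind, edges)
  nodes <- data.frame(id = seq_len(ncl), x_um = cl_pos[, 1],
                      y_um = cl_pos[, 2], z_um = cl_pos[, 3])
  ed <- if (is.null(edges)) data.frame(from = integer(0), to = integer(0)) else {
    edges <- edges[!is.na(edges[, 2]), , drop = FALSE]
    data.frame(from = edges[, 1], to = edges[, 2],
               path_length_um = edges[, 3])
  }
  skeleton_graph(nodes, ed, major_axis = major_axis)
}

#' Coarse-grain and prune a skeleton graph
#'
#' Applies the graph clean-up rules: (1) iteratively merge the globally
#' closest node pair below `merge_px` (in xy-plane pixel units; z is
#' scaled into the same units) to a node at their midpoint, recomputing
#' distances after every merge until no pair is closer; (2) remove
#' degree-1 end nodes whose single edge path is shorter than `prune_px`;
#' (3) dissolve the resulting degree-2 pass-through nodes, concatenating
#' their edge paths. An edge contracted by a merge disappears; parallel
#' edges between a merged pair survive as a self-loop, so cycle rank is
#' preserved by merging and dissolving.
#'
#' @param graph A [skeleton_graph()].
#' @param merge_px Merge radius in pixels (default 5).
#' @param prune_px End-edge rejection length in pixels (default 9).
#' @param pixel_size_xy Size of one xy pixel (um); node distances and path
#'   lengths are divided by this to apply the pixel rules.
#' @param dissolve Dissolve degree-2 nodes after pruning (default TRUE).
#' @return A simplified [skeleton_graph()].
#' @export
simplify_graph <- function(graph, merge_px = 5, prune_px = 9,
                           pixel_size_xy = 1, dissolve = TRUE) {
  nodes <- graph$nodes
  edges <- graph$edges[, c("from", "to", "path_length_um")]
  thr_merge <- merge_px * pixel_size_xy
  thr_prune <- prune_px * pixel_size_xy

  repeat {
    if (nrow(nodes) < 2L) break
    pos <- as.matrix(nodes[c("x_um", "y_um", "z_um")])
    D <- as.matrix(stats::dist(pos))
    diag(D) <- Inf
    if (min(D) >= thr_merge) break
    ij <- which(D == min(D), arr.ind = TRUE)[1, ]
    a <- nodes$id[ij[1]]; b <- nodes$id[ij[2]]
    mid <- (pos[ij[1], ] + pos[ij[2], ]) / 2
    nodes[ij[1], c("x_um", "y_um", "z_um")] <- mid
    nodes <- nodes[nodes$id != b, ]
    edges$from[edges$from == b] <- a
    edges$to[edges$to == b] <- a
    loop <- edges$from == a & edges$to == a
    if (any(loop)) {
      # one a-b edge is contracted by the merge; extra parallels stay as
      # self-loops
      drop <- which(loop)[1]
      edges <- edges[-drop, ]
    }
  }

  deg <- function() {
    tab <- table(factor(c(edges$from, edges$to), levels = nodes$id))
    stats::setNames(as.integer(tab), names(tab))
  }
  repeat {
    dg <- deg()
    ends <- nodes$id[dg[as.character(nodes$id)] == 1L]
    if (length(ends) == 0L) break
    drop_nodes <- c()
    drop_edges <- c()
    for (v in ends) {
      ei <- which(edges$from == v | edges$to == v)
      if (length(ei) == 1L && edges$path_length_um[ei] < thr_prune) {
        drop_nodes <- c(drop_nodes, v)
        drop_edges <- c(drop_edges, ei)
      }
    }
    if (length(drop_edges) == 0L) break
    edges <- edges[-unique(drop_edges), ]
    nodes <- nodes[!(nodes$id %in% drop_nodes), ]
    break  # single pruning pass, as in the published recipe
  }

  if (dissolve) {
    repeat {
      dg <- deg()
      mid <- nodes$id[dg[as.character(nodes$id)] == 2L]
      mid <- Filter(function(v) {
        ei <- which(edges$from == v | edges$to == v)
        length(ei) == 2L && !any(edges$from[ei] == edges$to[ei])
      }, mid)
      if (length(mid) == 0L) break
      v <- mid[[1]]
      ei <- which(edges$from == v | edges$to == v)
      o1 <- if (edges$from[ei[1]] == v) edges$to[ei[1]] else edges$from[ei[1]]
      o2 <- if (edges$from[ei[2]] == v) edges$to[ei[2]] else edges$from[ei[2]]
      newlen <- sum(edges$path_length_um[ei])
      edges <- edges[-ei, ]
      edges <- rbind(edges, data.frame(from = o1, to = o2,
                                       path_length_um = newlen))
      nodes <- nodes[nodes$id != v, ]
    }
  }
  skeleton_graph(nodes, edges, major_axis = graph$major_axis)
}

#' Network metrics of a skeleton graph
#'
#' Edge-length statistics, edge orientations relative to the cell's major
#' axis (unsigned, folded to `[0, pi/2]`; self-loops excluded), and the
#' topology: `beta1 = E - N + C` and genus `beta1/2`.
#'
#' @param graph A [skeleton_graph()].
#' @param major_axis Unit 3-vector; defaults to the graph's own.
#' @return A `network_metrics` list: `edge_lengths_um`,
#'   `mean_edge_length_um`, `orientation_rad`, `beta1`, `genus`,
#'   `n_nodes`, `n_edges`, `n_components`.
#' @export
network_metrics <- function(graph, major_axis = NULL) {
  if (is.null(major_axis)) major_axis <- graph$major_axis
  major_axis <- major_axis / sqrt(sum(major_axis^2))
  ed <- graph$edges
  lens <- ed$path_length_um
  chord <- as.matrix(ed[c("chord_x", "chord_y", "chord_z")])
  cn <- sqrt(rowSums(chord^2))
  ok <- cn > 0
  ang <- acos(pmin(abs(as.vector(chord[ok, , drop = FALSE] %*% major_axis)) /
                     cn[ok], 1))
  b1 <- graph_beta1(graph)
  structure(list(
    edge_lengths_um = lens,
    mean_edge_length_um = if (length(lens)) mean(lens) else NA_real_,
    orientation_rad = ang,
    beta1 = b1, genus = b1 / 2,
    n_nodes = nrow(graph$nodes), n_edges = nrow(ed),
    n_components = igraph::count_components(graph$graph)
  ), class = "network_metrics")
}

#' Major axis of a 2D mask from second central moments
#'
#' @param mask Logical matrix `[x, y]`.
#' @return Unit 2-vector (principal eigenvector of the covariance of
#'   foreground pixel coordinates).
#' @export
major_axis_from_mask <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) < 2) stop("mask too small for a major axis", call. = FALSE)
  ev <- eigen(stats::cov(idx))$vectors[, 1]
  ev / sqrt(sum(ev^2))
}
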