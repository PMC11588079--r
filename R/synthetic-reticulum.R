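#' Sample a ground-truth chloroplast reticulum graph
#'
#' Draws well-separated node positions in the cell body outside the core
#' interior (plus the core boundary), with a thin z-slab, and connects
#' them into a single spatial network whose edges are biased along the
#' cell's major axis: neighbors are found under an anisotropic metric that
#' shrinks the major-axis coordinate by `1 + axis_bias`, so long edges
#' preferentially run along the cell axis, emulating the long axial
#' cytoplasmic strands of the extended chloroplast. A minimum spanning
#' tree in the same metric guarantees connectivity; k-nearest-neighbor
#' edges add the cycles of the reticulum.
#'
#' @param geometry A [make_cell_geometry()].
#' @param n_nodes Number of nodes (>= 4).
#' @param axis_bias Anisotropy strength (0 = isotropic).
#' @param tube_radius Strand radius (um), carried to the renderer.
#' @param seed Integer seed (graph is reproducible bit-for-bit).
#' @param slab_depth_um Thickness of the z-slab containing the nodes.
#' @param k_neighbors Neighbors per node before the spanning tree union.
#' @return A [skeleton_graph()] with `tube_radius_um` and `slab_depth_um`
#'   attached as attributes.
#' @export
sample_reticulum <- function(geometry, n_nodes = 60, axis_bias = 1.5,
                             tube_radius = 1.2, seed = 1,
                             slab_depth_um = 8, k_neighbors = 3) {
  if (n_nodes < 4) stop("n_nodes must be >= 4", call. = FALSE)
  if (tube_radius <= 0) stop("tube_radius must be > 0", call. = FALSE)
  set.seed(seed)

  core_boundary <- geometry$core &
    !(shift_mask(geometry$core, 1, 0) & shift_mask(geometry$core, -1, 0) &
      shift_mask(geometry$core, 0, 1) & shift_mask(geometry$core, 0, -1))
  allowed <- (geometry$outer & !geometry$core) | core_boundary
  cand <- mask_coords_um(geometry, allowed)
  if (nrow(cand) < n_nodes)
    stop("n_nodes exceeds the raster capacity of the allowed region",
         call. = FALSE)

  # greedy Poisson-disc-like sampling for spatial spread
  d_min <- 0.6 * sqrt(nrow(cand) * geometry$pixel_size^2 / n_nodes)
  pts <- matrix(NA_real_, n_nodes, 2)
  n_acc <- 0L; tries <- 0L
  while (n_acc < n_nodes) {
    p <- cand[sample.int(nrow(cand), 1L), ]
    ok <- n_acc == 0L ||
      min(colSums((t(pts[seq_len(n_acc), , drop = FALSE]) - p)^2)) >= d_min^2
    if (ok) { n_acc <- n_acc + 1L; pts[n_acc, ] <- p }
    tries <- tries + 1L
    if (tries > 200L * n_nodes) { d_min <- d_min * 0.8; tries <- 0L }
  }
  jit <- matrix(stats::runif(2 * n_nodes, -0.5, 0.5), ncol = 2) *
    geometry$pixel_size
  pts <- pts + jit
  z <- stats::runif(n_nodes, 0.25 * slab_depth_um, 0.75 * slab_depth_um)

  scaled <- cbind(pts[, 1] / (1 + axis_bias), pts[, 2], z)
  D <- as.matrix(stats::dist(scaled))
  edges <- matrix(integer(0), 0, 2)
  for (i in seq_len(n_nodes)) {
    nb <- order(D[i, ])[2:(k_neighbors + 1L)]
    edges <- rbind(edges, cbind(pmin(i, nb), pmax(i, nb)))
  }
  full <- igraph::graph_from_adjacency_matrix(D, mode = "undirected",
                                              weighted = TRUE)
  mst <- igraph::mst(full)
  me <- igraph::as_edgelist(mst, names = FALSE)
  edges <- unique(rbind(edges, cbind(pmin(me[, 1], me[, 2]),
                                     pmax(me[, 1], me[, 2]))))

  nodes <- data.frame(id = seq_len(n_nodes), x_um = pts[, 1],
                      y_um = pts[, 2], z_um = z)
  g <- skeleton_graph(nodes,
                      data.frame(from = edges[, 1], to = edges[, 2]),
                      major_axis = c(geometry$major_axis, 0))
  attr(g, "tube_radius_um") <- tube_radius
  attr(g, "slab_depth_um") <- slab_depth_um
  g
}

# shift a logical matrix by (dx, dy), padding with FALSE
shift_mask <- function(m, dx, dy) {
  out <- matrix(FALSE, nrow(m), ncol(m))
  xs <- seq_len(nrow(m)); ys <- seq_len(ncol(m))
  xs_src <- xs - dx; ys_src <- ys - dy
  okx <- xs_src >= 1 & xs_src <= nrow(m)
  oky <- ys_src >= 1 & ys_src <= ncol(m)
  out[xs[okx], ys[oky]] <- m[xs_src[okx], ys_src[oky], drop = FALSE]
  out
}
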