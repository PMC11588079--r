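test_that("a straight tube skeletonizes to two end nodes and one edge", {
  tube <- rasterize_tube(c(40, 11, 9), a = c(4, 6, 5), b = c(36, 6, 5),
                         radius = 2.5)
  g <- skeletonize_to_graph(tube, c(x = 1, y = 1, z = 1))
  expect_equal(nrow(g$nodes), 2)
  expect_equal(nrow(g$edges), 1)
  expect_equal(g$edges$path_length_um, 32, tolerance = 2 / 32)
  expect_equal(graph_beta1(g), 0)
})

test_that("an X-shaped phantom yields one junction, four ends, four edges", {
  dims <- c(50, 50, 9)
  x1 <- rasterize_tube(dims, c(6, 6, 5), c(44, 44, 5), radius = 2)
  x2 <- rasterize_tube(dims, c(6, 44, 5), c(44, 6, 5), radius = 2)
  g <- skeletonize_to_graph(x1 | x2, c(x = 1, y = 1, z = 1))
  gs <- simplify_graph(g, merge_px = 5, prune_px = 9, pixel_size_xy = 1)
  dg <- igraph::degree(gs$graph)
  expect_equal(nrow(gs$nodes), 5)
  expect_equal(nrow(gs$edges), 4)
  expect_equal(sort(unname(dg)), c(1, 1, 1, 1, 4))
})

test_that("a rendered torus tube preserves its cycle", {
  # circular tube centered mid-volume
  n <- 41
  theta <- seq(0, 2 * pi, length.out = 73)
  ring <- array(FALSE, dim = c(n, n, 9))
  for (i in seq_len(length(theta) - 1)) {
    a <- c(21 + 14 * cos(theta[i]), 21 + 14 * sin(theta[i]), 5)
    b <- c(21 + 14 * cos(theta[i + 1]), 21 + 14 * sin(theta[i + 1]), 5)
    ring <- ring | rasterize_tube(dim(ring), a, b, radius = 2)
  }
  g <- skeletonize_to_graph(ring, c(x = 1, y = 1, z = 1))
  expect_equal(graph_beta1(g), 1)
})

test_that("coarse-graining and pruning follow the pixel rules", {
  mk <- function(nodes, edges) skeleton_graph(nodes, edges)
  # two nodes 3 px apart merge to their midpoint
  g <- mk(data.frame(id = 1:2, x_um = c(0, 3), y_um = 0, z_um = 0),
          data.frame(from = 1, to = 2))
  gs <- simplify_graph(g, pixel_size_xy = 1)
  expect_equal(nrow(gs$nodes), 1)
  expect_equal(gs$nodes$x_um, 1.5)
  # an end node on a 5 px edge is pruned; on a 12 px edge it stays
  g2 <- mk(data.frame(id = 1:4, x_um = c(0, 10, 20, 25), y_um = 0, z_um = 0),
           data.frame(from = c(1, 2, 3), to = c(2, 3, 4),
                      path_length_um = c(10, 10, 5)))
  gs2 <- simplify_graph(g2, pixel_size_xy = 1, dissolve = FALSE)
  expect_false(4 %in% gs2$nodes$id)
  g3 <- mk(data.frame(id = 1:3, x_um = c(0, 10, 22), y_um = 0, z_um = 0),
           data.frame(from = c(1, 2), to = c(2, 3),
                      path_length_um = c(10, 12)))
  gs3 <- simplify_graph(g3, pixel_size_xy = 1, dissolve = FALSE)
  expect_true(3 %in% gs3$nodes$id)
})

test_that("network metrics report lengths, orientations and topology", {
  tree <- skeleton_graph(
    data.frame(id = 1:5, x_um = c(0, 10, 20, 10, 10), y_um = c(0, 0, 0, 10, -10),
               z_um = 0),
    data.frame(from = c(1, 2, 2, 2), to = c(2, 3, 4, 5)))
  mt <- network_metrics(tree)
  expect_equal(mt$beta1, 0)
  expect_equal(mt$genus, 0)
  square <- skeleton_graph(
    data.frame(id = 1:4, x_um = c(0, 10, 10, 0), y_um = c(0, 0, 10, 10),
               z_um = 0),
    data.frame(from = c(1, 2, 3, 4), to = c(2, 3, 4, 1)))
  ms <- network_metrics(square)
  expect_equal(ms$beta1, 1)
  expect_equal(ms$genus, 0.5)
  expect_equal(ms$mean_edge_length_um, 10)
  axis_edge <- skeleton_graph(
    data.frame(id = 1:2, x_um = c(0, 5), y_um = 0, z_um = 0),
    data.frame(from = 1, to = 2))
  expect_equal(network_metrics(axis_edge)$orientation_rad, 0)
  # angles are folded: a reversed edge has the same orientation
  rev_edge <- skeleton_graph(
    data.frame(id = 1:2, x_um = c(5, 0), y_um = 0, z_um = 0),
    data.frame(from = 1, to = 2))
  expect_equal(network_metrics(rev_edge)$orientation_rad, 0)
})

test_that("beta1 survives simplification when pruning touches no cycle", {
  set.seed(31)
  for (rep in 1:15) {
    n <- sample(6:12, 1)
    # well-spaced random nodes (no accidental merges) on a 200 um field
    repeat {
      pos <- matrix(stats::runif(2 * n, 0, 200), ncol = 2)
      if (min(stats::dist(pos)) > 12) break
    }
    nodes <- data.frame(id = seq_len(n), x_um = pos[, 1], y_um = pos[, 2],
                        z_um = 0)
    # a random spanning tree plus extra chords creates cycles
    edges <- data.frame(from = 2:n, to = vapply(2:n, function(i)
      sample(seq_len(i - 1), 1), integer(1)))
    extra <- utils::combn(n, 2)[, sample(choose(n, 2), 2)]
    edges <- unique(rbind(edges, data.frame(from = pmin(extra[1, ], extra[2, ]),
                                            to = pmax(extra[1, ], extra[2, ]))))
    edges <- edges[edges$from != edges$to, ]
    g <- skeleton_graph(nodes, edges)
    b_before <- graph_beta1(g)
    gs <- simplify_graph(g, merge_px = 5, prune_px = 9, pixel_size_xy = 1)
    expect_equal(graph_beta1(gs), b_before)
  }
})

test_that("contraction shortens the longest edges but barely the mean", {
  geo <- make_cell_geometry()
  g <- sample_reticulum(geo, n_nodes = 80, axis_bias = 2, seed = 12)
  fld <- motion_field(0.35, c(geo$core_centroid_um, 4), 0, seed = 1)
  trk <- advect_network(g, fld, times = c(0, 2.5), geometry = NULL)
  lens_at <- function(f) {
    pos <- frame_positions(trk, f)
    a <- pos[as.character(g$edges$from), ]; b <- pos[as.character(g$edges$to), ]
    sqrt(rowSums((a - b)^2))
  }
  l0 <- lens_at(1); l1 <- lens_at(2)
  expect_lt(stats::quantile(l1, 0.95), stats::quantile(l0, 0.95))
  expect_lt(max(l1), max(l0) * exp(-0.35 * 2.5) * 1.05)
})

test_that("core jitter flattens an axis-biased orientation distribution", {
  geo <- make_cell_geometry(core_fraction = 0.7)
  g <- sample_reticulum(geo, n_nodes = 60, axis_bias = 2.5, seed = 21)
  fld <- motion_field(0.8, c(geo$core_centroid_um, 4),
                      core_diffusivity = 3, seed = 2)
  trk <- advect_network(g, fld, times = seq(0, 6, 0.5), geometry = geo)
  ang_at <- function(f) {
    pos <- frame_positions(trk, f)
    ch <- pos[as.character(g$edges$to), 1:2] -
      pos[as.character(g$edges$from), 1:2]
    acos(pmin(abs(ch[, 1]) / sqrt(rowSums(ch^2)), 1))
  }
  ks0 <- stats::ks.test(ang_at(1), "punif", 0, pi / 2)$statistic
  ks1 <- stats::ks.test(ang_at(13), "punif", 0, pi / 2)$statistic
  expect_lt(ks1, ks0)  # closer to uniform after compaction
})
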