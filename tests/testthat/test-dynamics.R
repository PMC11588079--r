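test_that("well-separated stationary points track into full trajectories", {
  pts <- matrix(c(0, 0, 0, 50, 0, 0, 0, 50, 0), ncol = 3, byrow = TRUE)
  frames <- rep(list(pts), 8)
  tr <- track_nodes(frames, frame_times_s = 0:7 * 10)
  expect_equal(length(unique(tr$traj_id)), 3)
  expect_true(all(table(tr$traj_id) == 8))
})

test_that("velocity prediction keeps a moving point in one trajectory", {
  frames <- lapply(0:9, function(f) matrix(c(5 * f, 0, 0), 1))
  tr <- track_nodes(frames)
  expect_equal(length(unique(tr$traj_id)), 1)
  expect_equal(nrow(tr), 10)
  # matches the brute-force optimal assignment oracle
  orc <- oracle_link(frames)
  expect_equal(length(orc), 1)
  expect_equal(unname(tr[c("x_um")][[1]]), unname(orc[[1]][, 2]))
})

test_that("memory bridges detection gaps up to four frames", {
  pos <- lapply(0:9, function(f) matrix(c(2 * f, 1, 0), 1))
  pos[5:7] <- list(matrix(numeric(0), 0, 3))  # missing for 3 frames
  tr <- track_nodes(pos, memory = 4)
  expect_equal(length(unique(tr$traj_id)), 1)
  expect_equal(nrow(tr), 7)
  # with memory 1 the track is split
  tr2 <- track_nodes(pos, memory = 1)
  expect_equal(length(unique(tr2$traj_id)), 2)
})

test_that("linking equals exhaustive optimal assignment on small scenes", {
  set.seed(17)
  for (rep in 1:10) {
    n <- sample(2:5, 1)
    start <- matrix(stats::runif(3 * n, 0, 60), ncol = 3)
    start[, 3] <- start[, 3] / 10
    vel <- matrix(stats::runif(3 * n, -1.5, 1.5), ncol = 3)
    vel[, 3] <- vel[, 3] / 5
    frames <- lapply(0:5, function(f) start + f * vel)
    tr <- track_nodes(frames)
    orc <- oracle_link(frames)
    expect_equal(length(unique(tr$traj_id)), length(orc))
    expect_true(all(table(tr$traj_id) == 6))
  }
})

test_that("the nine-step rule rejects short trajectories", {
  set <- data.frame(traj_id = rep(c(1, 2), c(8, 9)), frame = c(1:8, 1:9),
                    time_s = c(1:8, 1:9) * 10,
                    x_um = 0, y_um = 0, z_um = 0)
  kept <- filter_trajectories(set)
  expect_equal(unique(kept$traj_id), 2)
  empty <- filter_trajectories(set[0, ])
  expect_equal(nrow(empty), 0)
})

test_that("Savitzky-Golay velocities are exact on polynomial paths", {
  tt <- seq(0, 120, by = 5)
  v <- c(1.2, -0.6, 0.3)  # um/s
  traj <- data.frame(time_s = tt, x_um = v[1] * tt, y_um = v[2] * tt,
                     z_um = v[3] * tt)
  vel <- trajectory_velocities(traj, window_s = 37.5)
  expect_equal(vel$speed_um_min, rep(sqrt(sum(v^2)) * 60, length(tt)),
               tolerance = 1e-10)
  # quadratic path: linear speed profile, exact for order-2 fits
  traj2 <- data.frame(time_s = tt, x_um = 0.01 * tt^2, y_um = 0, z_um = 0)
  vel2 <- trajectory_velocities(traj2, window_s = 37.5)
  expect_equal(vel2$vx, 0.02 * tt * 60, tolerance = 1e-8)
  still <- data.frame(time_s = tt, x_um = 1, y_um = 2, z_um = 3)
  expect_equal(trajectory_velocities(still)$speed_um_min,
               rep(0, length(tt)))
  expect_error(trajectory_velocities(traj[1:5, ], window_s = 37.5),
               "window")
})

test_that("MSD is exactly ballistic for uniform motion and zero at rest", {
  tt <- seq(0, 200, 10)
  v <- c(0.3, 0.4, 0)
  traj <- data.frame(time_s = tt, x_um = v[1] * tt, y_um = v[2] * tt, z_um = 0)
  msd <- msd_curve(traj)
  expect_equal(msd$msd_um2, 0.25 * msd$tau_s^2, tolerance = 1e-12)
  expect_equal(msd_slope(msd), 2, tolerance = 1e-10)
  expect_true(all(msd$tau_s <= (max(tt) - min(tt)) / 2))
  still <- data.frame(time_s = tt, x_um = 1, y_um = 1, z_um = 1)
  expect_true(all(msd_curve(still)$msd_um2 == 0))
})

test_that("simulated random walks recover the diffusive MSD slope", {
  set.seed(23)
  slopes <- replicate(100, {
    n <- 200
    pos <- apply(matrix(stats::rnorm(3 * n, 0, 0.5), ncol = 3), 2, cumsum)
    traj <- data.frame(time_s = seq_len(n) * 10, x_um = pos[, 1],
                       y_um = pos[, 2], z_um = pos[, 3])
    msd_slope(msd_curve(traj))
  })
  expect_equal(mean(slopes), 1, tolerance = 0.1)
})

test_that("distance map is geodesic within the mask", {
  strip <- matrix(FALSE, 30, 3)
  strip[, 2] <- TRUE
  d <- distance_map(strip, c(1, 2))
  expect_equal(d[cbind(1:30, 2)], 0:29)
  expect_equal(d[5, 2], 4)
  expect_true(all(is.na(d[, 1])))
  expect_error(distance_map(strip, c(1, 1)), "outside")
  # C-shaped mask: geodesic tip-to-tip exceeds the Euclidean distance,
  # and matches a Dijkstra oracle on the pixel graph
  cmask <- annulus_mask(10, 5)
  cmask[16:21, 11:21] <- FALSE  # cut the ring open on one side
  start <- c(18, 9)
  stopifnot(cmask[start[1], start[2]])
  d2 <- distance_map(cmask, start)
  idx <- which(cmask, arr.ind = TRUE)
  g <- igraph::make_empty_graph(n = nrow(idx), directed = FALSE)
  key <- paste(idx[, 1], idx[, 2])
  lookup <- stats::setNames(seq_len(nrow(idx)), key)
  eds <- c(); ws <- c()
  for (k in seq_len(nrow(idx))) {
    for (o in list(c(1, 0, 1), c(0, 1, 1), c(1, 1, sqrt(2)), c(1, -1, sqrt(2)))) {
      nb <- lookup[paste(idx[k, 1] + o[1], idx[k, 2] + o[2])]
      if (!is.na(nb)) { eds <- c(eds, k, nb); ws <- c(ws, o[3]) }
    }
  }
  g <- igraph::add_edges(g, eds, weight = ws)
  d_or <- igraph::distances(g, v = lookup[paste(start[1], start[2])])[1, ]
  expect_equal(d2[idx], unname(d_or), tolerance = 1e-9)
  far <- idx[which.max(d_or), ]
  eucl <- sqrt(sum((far - start)^2))
  expect_gt(max(d_or), eucl * 1.5)
})

test_that("affine contraction yields v = k D and a flat strain-rate plateau", {
  set.seed(3)
  k <- 0.3  # min^-1
  n <- 25
  start <- cbind(stats::runif(n, -60, 60), stats::runif(n, -25, 25), 0)
  tt <- seq(0, 120, 10)  # seconds
  frames <- lapply(tt, function(t) start * exp(-k * t / 60))
  tr <- track_nodes(frames, frame_times_s = tt)
  tr <- filter_trajectories(tr)
  an <- speed_distance_analysis(tr, center_um = c(0, 0))
  expect_equal(an$slope_min, k, tolerance = 0.02)
  expect_lt(an$plateau_rel_sd, 0.05)
  # stationary nodes have zero speed at any distance
  fr_still <- rep(list(start), 13)
  tr2 <- filter_trajectories(track_nodes(fr_still, frame_times_s = tt))
  an2 <- speed_distance_analysis(tr2, center_um = c(0, 0))
  expect_lt(max(an2$table$speed_um_min), 1e-8)
})

test_that("a diffusive core plus ballistic rim gives heavy-tailed speeds", {
  skip_if_not_installed("e1071")
  set.seed(41)
  tt <- seq(0, 240, 10)
  mk_ball <- function(r0) {
    d <- r0 / sqrt(2)
    t(vapply(tt, function(t) c(d, d, 0) * exp(-0.4 * t / 60), numeric(3)))
  }
  mk_diff <- function() {
    step <- matrix(stats::rnorm(3 * length(tt), 0, 0.12), ncol = 3)
    step[, 3] <- 0
    apply(step, 2, cumsum)
  }
  trajs <- c(lapply(c(40, 55, 70, 85, 100), mk_ball),
             replicate(20, mk_diff(), simplify = FALSE))
  set <- do.call(rbind, lapply(seq_along(trajs), function(i)
    data.frame(traj_id = i, frame = seq_along(tt), time_s = tt,
               x_um = trajs[[i]][, 1], y_um = trajs[[i]][, 2],
               z_um = trajs[[i]][, 3])))
  an <- speed_distance_analysis(set, center_um = c(0, 0))
  expect_gt(e1071::kurtosis(an$table$speed_um_min), 0)
})
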