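#' Savitzky-Golay velocities along a trajectory
#'
#' Fits local second-order polynomials in a sliding window (default the
#' odd sample count nearest to 37.5 s, the midpoint of the 30-45 s
#' recipe) and takes their analytic first derivative, per coordinate.
#' Exact for polynomial paths up to the fit order. Trajectories with
#' interior gaps are linearly resampled onto the regular frame grid
#' before filtering.
#'
#' @param traj One trajectory: a data frame with `time_s`, `x_um`,
#'   `y_um`, `z_um` (one `traj_id`).
#' @param window_s Target window length in seconds (30-45 recommended).
#' @param poly_order Polynomial order (default 2).
#' @return A data frame `time_s`, `vx`, `vy`, `vz`, `speed_um_min`
#'   (speeds in um/min) on the regular grid spanning the trajectory.
#' @export
trajectory_velocities <- function(traj, window_s = 37.5, poly_order = 2) {
  tt <- traj$time_s
  if (length(tt) < 3) stop("trajectory too short", call. = FALSE)
  dt <- min(diff(sort(unique(tt))))
  grid <- seq(min(tt), max(tt), by = dt)
  if (max(tt) - min(tt) <= window_s)
    stop("trajectory duration must exceed the smoothing window", call. = FALSE)
  n <- round(window_s / dt)
  if (n %% 2 == 0) n <- n + 1L
  n <- max(n, poly_order + 1 + (poly_order %% 2 == 0))
  if (n %% 2 == 0) n <- n + 1L
  if (n > length(grid))
    stop("trajectory has fewer samples than the smoothing window", call. = FALSE)
  pos <- vapply(c("x_um", "y_um", "z_um"), function(cn)
    stats::approx(tt, traj[[cn]], xout = grid)$y, numeric(length(grid)))
  v <- apply(pos, 2, function(x)
    signal::sgolayfilt(x, p = poly_order, n = n, m = 1, ts = dt / 60))
  v <- matrix(v, ncol = 3)
  data.frame(time_s = grid, vx = v[, 1], vy = v[, 2], vz = v[, 3],
             speed_um_min = sqrt(rowSums(v^2)))
}

#' Time-averaged mean squared displacement of a trajectory
#'
#' `MSD(tau) = < |x(t + tau) - x(t)|^2 >_t` over all sample pairs with
#' lag `tau`, for lags up to half the trajectory duration. Slope 1 of
#' `log MSD` vs `log tau` indicates diffusive, slope 2 ballistic motion.
#'
#' @param traj One trajectory (data frame with `time_s`, `x_um`, `y_um`,
#'   `z_um`).
#' @return An `msd_curve` data frame: `tau_s`, `msd_um2`, `n_pairs`.
#' @export
msd_curve <- function(traj) {
  tt <- traj$time_s
  if (length(tt) < 2) stop("need at least 2 points", call. = FALSE)
  pos <- as.matrix(traj[c("x_um", "y_um", "z_um")])
  dt <- min(diff(sort(unique(tt))))
  steps <- round((tt - tt[1]) / dt)
  T_half <- (max(tt) - min(tt)) / 2
  max_lag <- floor(T_half / dt)
  res <- lapply(seq_len(max_lag), function(lag) {
    i <- match(steps + lag, steps)
    ok <- !is.na(i)
    if (!any(ok)) return(NULL)
    d2 <- rowSums((pos[i[ok], , drop = FALSE] - pos[ok, , drop = FALSE])^2)
    data.frame(tau_s = lag * dt, msd_um2 = mean(d2), n_pairs = sum(ok))
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(tau_s = numeric(0), msd_um2 = numeric(0),
                      n_pairs = integer(0))
  class(out) <- c("msd_curve", "data.frame")
  out
}

#' Log-log slope of an MSD curve
#'
#' @param msd An [msd_curve()] result (zero-MSD lags are dropped).
#' @return Least-squares slope of `log(msd)` on `log(tau)`.
#' @export
msd_slope <- function(msd) {
  ok <- msd$msd_um2 > 0
  if (sum(ok) < 2) return(NA_real_)
  stats::coef(stats::lm(log(msd$msd_um2[ok]) ~ log(msd$tau_s[ok])))[[2]]
}

#' Geodesic distance map within a mask
#'
#' Distance from a center pixel measured along paths inside the mask
#' (8-connected, with diagonal steps weighted sqrt(2)), computed by
#' iterated chamfer sweeps to convergence. Off-mask pixels are `NA`.
#'
#' @param mask Logical matrix `[x, y]`.
#' @param center Pixel indices `c(ix, iy)` of the center; must lie inside
#'   the mask.
#' @param pixel_size Pixel size (um/px); distances are returned in um.
#' @return Numeric matrix of geodesic distances (`NA` off-mask).
#' @export
distance_map <- function(mask, center, pixel_size = 1) {
  if (!mask[center[1], center[2]])
    stop("center pixel is outside the mask", call. = FALSE)
  nx <- nrow(mask); ny <- ncol(mask)
  d <- matrix(Inf, nx, ny)
  d[center[1], center[2]] <- 0
  w_ax <- 1; w_di <- sqrt(2)
  repeat {
    changed <- FALSE
    for (sweep_dir in 1:2) {
      xs <- if (sweep_dir == 1) seq_len(nx) else rev(seq_len(nx))
      ys <- if (sweep_dir == 1) seq_len(ny) else rev(seq_len(ny))
      for (j in ys) for (i in xs) {
        if (!mask[i, j]) next
        best <- d[i, j]
        for (o in list(c(-1, 0, w_ax), c(1, 0, w_ax), c(0, -1, w_ax),
                       c(0, 1, w_ax), c(-1, -1, w_di), c(-1, 1, w_di),
                       c(1, -1, w_di), c(1, 1, w_di))) {
          ii <- i + o[1]; jj <- j + o[2]
          if (ii < 1 || ii > nx || jj < 1 || jj > ny || !mask[ii, jj]) next
          cand <- d[ii, jj] + o[3]
          if (cand < best) best <- cand
        }
        if (best < d[i, j] - 1e-12) { d[i, j] <- best; changed <- TRUE }
      }
    }
    if (!changed) break
  }
  d[!mask] <- NA_real_
  d[is.infinite(d)] <- NA_real_
  d * pixel_size
}

#' Speed-distance (strain-rate) analysis of tracked nodes
#'
#' Joins per-point Savitzky-Golay speeds with the distance of each
#' observation from the contraction center, computes the local strain
#' rate `v/D`, a through-origin regression slope of `v` on `D` (the
#' affine-contraction rate), a log-binned `v` vs `D` summary, and a
#' plateau statistic: the relative SD of `v/D` over the upper half of the
#' distance range (small values mean `v` is proportional to `D`, i.e.
#' affine elastic-like contraction).
#'
#' @param set A filtered `trajectory_set`.
#' @param dmap Distance raster from [distance_map()] (um), or `NULL` to
#'   use the Euclidean distance from `center_um`.
#' @param origin_um Physical coordinates of raster pixel (1,1) when
#'   `dmap` is used.
#' @param pixel_size Raster pixel size (um/px) when `dmap` is used.
#' @param center_um Length-2 center for Euclidean distances.
#' @param window_s,poly_order Passed to [trajectory_velocities()].
#' @param n_bins Number of logarithmic distance bins in the summary.
#' @return A list with `table` (columns `traj_id`, `time_s`,
#'   `distance_um`, `speed_um_min`, `strain_rate_min`), `slope_min`
#'   (`v = slope * D`, min^-1), `plateau_rel_sd`, and `binned`.
#' @export
speed_distance_analysis <- function(set, dmap = NULL, origin_um = c(0, 0),
                                    pixel_size = 1, center_um = c(0, 0),
                                    window_s = 37.5, poly_order = 2,
                                    n_bins = 8) {
  ids <- unique(set$traj_id)
  rows <- lapply(ids, function(id) {
    tr <- set[set$traj_id == id, ]
    vel <- tryCatch(trajectory_velocities(tr, window_s, poly_order),
                    error = function(e) NULL)
    if (is.null(vel)) return(NULL)
    x <- stats::approx(tr$time_s, tr$x_um, xout = vel$time_s)$y
    y <- stats::approx(tr$time_s, tr$y_um, xout = vel$time_s)$y
    if (is.null(dmap)) {
      D <- sqrt((x - center_um[1])^2 + (y - center_um[2])^2)
    } else {
      ix <- pmin(pmax(round((x - origin_um[1]) / pixel_size) + 1L, 1L),
                 nrow(dmap))
      iy <- pmin(pmax(round((y - origin_um[2]) / pixel_size) + 1L, 1L),
                 ncol(dmap))
      D <- dmap[cbind(ix, iy)]
    }
    data.frame(traj_id = id, time_s = vel$time_s, distance_um = D,
               speed_um_min = vel$speed_um_min,
               strain_rate_min = ifelse(D > 0, vel$speed_um_min / D, NA_real_))
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab) || nrow(tab) == 0L)
    stop("no trajectory long enough for velocity estimation", call. = FALSE)
  ok <- is.finite(tab$distance_um) & is.finite(tab$speed_um_min)
  tab <- tab[ok, ]
  slope <- stats::coef(stats::lm(speed_um_min ~ 0 + distance_um, data = tab))[[1]]
  upper <- tab$distance_um > max(tab$distance_um) / 2
  sr <- tab$strain_rate_min[upper & is.finite(tab$strain_rate_min)]
  plateau <- if (length(sr) > 1) stats::sd(sr) / mean(sr) else NA_real_
  dpos <- tab$distance_um[tab$distance_um > 0]
  brks <- exp(seq(log(max(min(dpos), 1e-6)), log(max(dpos)),
                  length.out = n_bins + 1))
  bin <- cut(tab$distance_um, breaks = unique(c(0, brks)),
             include.lowest = TRUE)
  binned <- do.call(rbind, lapply(split(tab, bin), function(g) {
    if (nrow(g) == 0L) return(NULL)
    data.frame(distance_um = mean(g$distance_um),
               speed_mean = mean(g$speed_um_min),
               speed_sd = stats::sd(g$speed_um_min), n = nrow(g))
  }))
  list(table = tab, slope_min = slope, plateau_rel_sd = plateau,
       binned = binned)
}
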