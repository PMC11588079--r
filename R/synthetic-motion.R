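#' Affine contraction motion field
#'
#' The kinematic model of chloroplast contraction: every node moves with
#' velocity `-k * (position - center)` (an affine inward flow, so speed is
#' proportional to distance from the center -- constant strain rate), and
#' nodes currently inside the cytoplasmic core additionally jitter
#' diffusively with diffusivity `core_diffusivity`. This reproduces the
#' observed dichotomy of ballistic peripheral nodes and diffusive central
#' nodes.
#'
#' @param strain_rate Contraction rate `k` (min^-1, >= 0).
#' @param center Contraction center, length-3 (um).
#' @param core_diffusivity Diffusivity inside the core (um^2/min, >= 0).
#' @param seed Integer seed for the jitter.
#' @return A `motion_field` list.
#' @export
motion_field <- function(strain_rate = 0.35, center = c(0, 0, 0),
                         core_diffusivity = 0.5, seed = 1) {
  if (strain_rate < 0 || core_diffusivity < 0)
    stop("strain_rate and core_diffusivity must be >= 0", call. = FALSE)
  structure(list(strain_rate = strain_rate,
                 center = rep_len(as.numeric(center), 3L),
                 core_diffusivity = core_diffusivity, seed = seed),
            class = "motion_field")
}

#' Instantaneous velocity of the motion field
#'
#' @param field A [motion_field()].
#' @param pos n x 3 matrix of positions (um).
#' @return n x 3 matrix of velocities (um/min); speed is exactly
#'   `k * distance-from-center`.
#' @export
motion_velocity <- function(field, pos) {
  pos <- matrix(pos, ncol = 3)
  -field$strain_rate * sweep(pos, 2, field$center)
}

#' Advect a reticulum graph through the contraction field
#'
#' Node positions are propagated exactly between frames under the affine
#' flow (`pos -> center + (pos - center) * exp(-k * dt)`), and nodes lying
#' inside the core region (xy test against `geometry$core`, when a
#' geometry is supplied) receive Brownian increments of variance
#' `2 * core_diffusivity * dt` per axis. Edges follow their nodes; the
#' graph is never rewired, so its topology (beta1) is identical in every
#' frame.
#'
#' @param graph A [skeleton_graph()].
#' @param field A [motion_field()].
#' @param times Strictly increasing frame times (min).
#' @param geometry Optional [make_cell_geometry()] defining the core
#'   region; without it no jitter is applied.
#' @return A `node_tracks` data frame with columns `frame`, `time_min`,
#'   `id`, `x_um`, `y_um`, `z_um`.
#' @export
advect_network <- function(graph, field, times, geometry = NULL) {
  if (any(diff(times) <= 0)) stop("times must be increasing", call. = FALSE)
  set.seed(field$seed)
  pos <- node_positions(graph)
  n <- nrow(pos)
  out <- vector("list", length(times))
  out[[1]] <- data.frame(frame = 1L, time_min = times[1], id = graph$nodes$id,
                         x_um = pos[, 1], y_um = pos[, 2], z_um = pos[, 3])
  for (f in seq_along(times)[-1]) {
    dt <- times[f] - times[f - 1]
    shrink <- exp(-field$strain_rate * dt)
    pos <- sweep(sweep(pos, 2, field$center) * shrink, 2, field$center, "+")
    if (!is.null(geometry) && field$core_diffusivity > 0) {
      in_core <- points_in_mask(geometry, pos[, 1:2, drop = FALSE], "core")
      if (any(in_core)) {
        sdj <- sqrt(2 * field$core_diffusivity * dt)
        pos[in_core, ] <- pos[in_core, , drop = FALSE] +
          matrix(stats::rnorm(3 * sum(in_core), 0, sdj), ncol = 3)
      }
    }
    out[[f]] <- data.frame(frame = f, time_min = times[f], id = graph$nodes$id,
                           x_um = pos[, 1], y_um = pos[, 2], z_um = pos[, 3])
  }
  res <- do.call(rbind, out)
  class(res) <- c("node_tracks", "data.frame")
  res
}

#' Node positions of one frame of a `node_tracks` table
#' @param tracks A `node_tracks` data frame from [advect_network()].
#' @param frame Frame index.
#' @return n x 3 matrix of positions (um), rownames = node ids.
#' @export
frame_positions <- function(tracks, frame) {
  fr <- tracks[tracks$frame == frame, ]
  m <- as.matrix(fr[c("x_um", "y_um", "z_um")])
  rownames(m) <- fr$id
  m
}
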