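#' Link node positions across frames into trajectories
#'
#' A velocity-predictive nearest-neighbor linker in the style of
#' trackpy's `link` with prediction: each active trajectory is
#' extrapolated at constant velocity from its previous displacement, and
#' new points are matched inside an anisotropic search window (default
#' (6, 6, 2) um) around the predicted position. Trajectories that miss
#' detections persist for up to `memory` frames before being closed (gap
#' closing). Ambiguous components -- where several tracks and points
#' share candidates -- are resolved by shrinking the window geometrically
#' (factor `adaptive_step` per conflict) down to `adaptive_floor` of its
#' initial extent, then taking the maximum-cardinality matching of
#' minimal total squared displacement by local exhaustive enumeration,
#' which makes the linker deterministic and oracle-comparable.
#'
#' @param frames List of per-frame point matrices (n_i x 3, um), or a
#'   `node_tracks` data frame from [advect_network()] (ids are ignored;
#'   tracking rebuilds identity).
#' @param search_window_um Half-extents of the search window (x, y, z),
#'   um.
#' @param memory Maximal number of consecutive missed frames.
#' @param adaptive_floor Smallest window fraction during conflict
#'   resolution.
#' @param adaptive_step Geometric shrink factor per conflict round.
#' @param frame_times_s Frame times (s); default `0, 10, 20, ...`.
#' @return A `trajectory_set` data frame: `traj_id`, `frame`, `time_s`,
#'   `x_um`, `y_um`, `z_um`.
#' @export
track_nodes <- function(frames, search_window_um = c(6, 6, 2), memory = 4,
                        adaptive_floor = 0.1, adaptive_step = 0.8,
                        frame_times_s = NULL) {
  if (inherits(frames, "data.frame")) {
    fr_ids <- sort(unique(frames$frame))
    frames <- lapply(fr_ids, function(f) {
      m <- as.matrix(frames[frames$frame == f, c("x_um", "y_um", "z_um")])
      rownames(m) <- NULL
      m
    })
  }
  n_frames <- length(frames)
  if (n_frames < 2) stop("need at least 2 frames to track", call. = FALSE)
  if (is.null(frame_times_s)) frame_times_s <- (seq_len(n_frames) - 1) * 10
  w <- as.numeric(search_window_um)

  # track state: list of (pts = matrix of rows c(frame, x, y, z))
  tracks <- list()
  last_seen <- integer(0)
  add_point <- function(ti, frame, p) {
    tracks[[ti]] <<- rbind(tracks[[ti]], c(frame, p))
    last_seen[ti] <<- frame
  }
  new_track <- function(frame, p) {
    tracks[[length(tracks) + 1L]] <<- matrix(c(frame, p), nrow = 1)
    last_seen[length(tracks)] <<- frame
  }
  pts0 <- frames[[1]]
  for (i in seq_len(nrow(pts0))) new_track(1L, pts0[i, ])

  predict_pos <- function(ti, frame) {
    m <- tracks[[ti]]
    k <- nrow(m)
    if (k == 1L) return(m[1, 2:4])
    v <- (m[k, 2:4] - m[k - 1, 2:4]) / (m[k, 1] - m[k - 1, 1])
    m[k, 2:4] + v * (frame - m[k, 1])
  }

  for (f in 2:n_frames) {
    pts <- frames[[f]]
    np <- if (is.null(pts)) 0L else nrow(pts)
    active <- which(f - last_seen <= memory + 1L & last_seen < f)
    if (np == 0L) next
    if (length(active) == 0L) {
      for (i in seq_len(np)) new_track(f, pts[i, ])
      next
    }
    pred <- t(vapply(active, predict_pos, numeric(3), frame = f))

    cand_at <- function(s) {
      lapply(seq_along(active), function(a) {
        dd <- abs(sweep(pts, 2, pred[a, ]))
        which(dd[, 1] <= w[1] * s & dd[, 2] <= w[2] * s & dd[, 3] <= w[3] * s)
      })
    }
    cand <- cand_at(1)
    # connected conflict components over (tracks, points)
    assign_track <- rep(NA_integer_, length(active))  # point index per track
    comp_of <- function(cand) {
      gid <- rep(NA_integer_, length(active))
      pid <- rep(NA_integer_, np)
      cid <- 0L
      for (a in seq_along(active)) {
        if (!is.na(gid[a]) || length(cand[[a]]) == 0L) next
        cid <- cid + 1L
        qa <- a
        while (length(qa)) {
          x <- qa[1]; qa <- qa[-1]
          if (!is.na(gid[x])) next
          gid[x] <- cid
          for (p in cand[[x]]) {
            if (!is.na(pid[p])) next
            pid[p] <- cid
            qa <- c(qa, which(vapply(cand, function(cc) p %in% cc,
                                     logical(1)) & is.na(gid)))
          }
        }
      }
      list(gid = gid, pid = pid, n = cid)
    }
    cp <- comp_of(cand)
    for (cid in seq_len(cp$n)) {
      aa <- which(cp$gid == cid)
      s <- 1
      sub <- lapply(cand[aa], function(x) x)
      ambiguous <- function(sub) {
        pts_used <- unlist(sub)
        any(lengths(sub) > 1L) || any(duplicated(pts_used))
      }
      while (ambiguous(sub) && s * adaptive_step >= adaptive_floor) {
        s <- s * adaptive_step
        sub <- cand_at(s)[aa]
      }
      # optimal matching among remaining candidates (exhaustive, small)
      best <- NULL; best_card <- -1L; best_cost <- Inf
      nA <- length(aa)
      rec <- function(i, used, cur, card, cost) {
        if (cost >= best_cost && card + (nA - i + 1L) <= best_card) return()
        if (i > nA) {
          if (card > best_card || (card == best_card && cost < best_cost)) {
            best <<- cur; best_card <<- card; best_cost <<- cost
          }
          return()
        }
        opts <- setdiff(sub[[i]], used)
        rec(i + 1L, used, c(cur, NA_integer_), card, cost)
        for (p in opts) {
          d2 <- sum((pts[p, ] - pred[aa[i], ])^2)
          rec(i + 1L, c(used, p), c(cur, p), card + 1L, cost + d2)
        }
      }
      rec(1L, integer(0), integer(0), 0L, 0)
      assign_track[aa] <- best
    }
    taken <- assign_track[!is.na(assign_track)]
    for (a in seq_along(active))
      if (!is.na(assign_track[a]))
        add_point(active[a], f, pts[assign_track[a], ])
    for (p in setdiff(seq_len(np), taken)) new_track(f, pts[p, ])
  }

  out <- do.call(rbind, lapply(seq_along(tracks), function(ti) {
    m <- tracks[[ti]]
    data.frame(traj_id = ti, frame = as.integer(m[, 1]),
               time_s = frame_times_s[m[, 1]],
               x_um = m[, 2], y_um = m[, 3], z_um = m[, 4])
  }))
  class(out) <- c("trajectory_set", "data.frame")
  out
}

#' Reject short trajectories
#'
#' Keeps only trajectories observed at at least `min_steps` time steps
#' (default 9, about 90-120 s at typical confocal frame rates).
#'
#' @param set A `trajectory_set` from [track_nodes()].
#' @param min_steps Minimal number of observations.
#' @return Filtered `trajectory_set`.
#' @export
filter_trajectories <- function(set, min_steps = 9) {
  if (nrow(set) == 0L) return(set)
  n <- table(set$traj_id)
  keep <- names(n)[n >= min_steps]
  out <- set[set$traj_id %in% keep, ]
  class(out) <- c("trajectory_set", "data.frame")
  out
}
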