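# Fixtures and independent oracles, built in code at test time.

# Independent fixed-step RK4 integrator for the full two-sensor model,
# written from the equations directly (no reuse of package internals).
oracle_rk4 <- function(protocol, params, x0 = 0, c1_0 = 0, c2_0 = params$alpha2,
                       dt = 1e-3) {
  deriv <- function(I, s) {
    s1 <- params$alpha1 * I
    s2 <- params$alpha2 * (I < params$i_th)
    dc1 <- (s1 - s[2]) / params$tau1
    dc2 <- (s2 - s[3]) / params$tau2
    p <- min(max(params$beta * (s[2] - s[3]), 0), params$x_max)
    tau <- if (p >= s[1]) params$tau_kv else params$tau_kv_star
    c((p - s[1]) / tau, dc1, dc2)
  }
  tt <- 0; xx <- x0; cc1 <- c1_0; cc2 <- c2_0
  s <- c(x0, c1_0, c2_0)
  # integrate per segment so no RK4 step straddles a light switch
  for (k in seq_len(nrow(protocol))) {
    I <- protocol$irradiance[k]
    dur <- protocol$t_end[k] - protocol$t_start[k]
    n <- ceiling(dur / dt)
    h <- dur / n
    for (i in seq_len(n)) {
      k1 <- deriv(I, s)
      k2 <- deriv(I, s + h / 2 * k1)
      k3 <- deriv(I, s + h / 2 * k2)
      k4 <- deriv(I, s + h * k3)
      s <- s + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      s[1] <- min(max(s[1], 0), params$x_max)
      tt <- c(tt, protocol$t_start[k] + i * h)
      xx <- c(xx, s[1]); cc1 <- c(cc1, s[2]); cc2 <- c(cc2, s[3])
    }
  }
  list(time = tt, x = xx, c1 = cc1, c2 = cc2,
       at = function(t) stats::approx(tt, xx, xout = t)$y)
}

# voxel rasters of simple topological phantoms
disc_mask <- function(r = 10, pad = 3) {
  n <- 2 * (r + pad) + 1
  c0 <- r + pad + 1
  outer(seq_len(n), seq_len(n),
        function(i, j) (i - c0)^2 + (j - c0)^2 <= r^2)
}

annulus_mask <- function(r_out = 12, r_in = 6, pad = 3) {
  n <- 2 * (r_out + pad) + 1
  c0 <- r_out + pad + 1
  d2 <- outer(seq_len(n), seq_len(n), function(i, j) (i - c0)^2 + (j - c0)^2)
  d2 <= r_out^2 & d2 > r_in^2
}

solid_torus_array <- function(R = 8, r = 3, pad = 3) {
  n <- 2 * (R + r + pad) + 1
  nz <- 2 * (r + pad) + 1
  c0 <- R + r + pad + 1
  cz <- r + pad + 1
  arr <- array(FALSE, dim = c(n, n, nz))
  for (k in seq_len(nz)) {
    dz <- k - cz
    arr[, , k] <- outer(seq_len(n), seq_len(n), function(i, j) {
      rho <- sqrt((i - c0)^2 + (j - c0)^2)
      (rho - R)^2 + dz^2 <= r^2
    })
  }
  arr
}

# tube of given radius around a 3D segment, on a voxel grid of size dims
rasterize_tube <- function(dims, a, b, radius) {
  arr <- array(FALSE, dim = dims)
  idx <- as.matrix(expand.grid(x = seq_len(dims[1]), y = seq_len(dims[2]),
                               z = seq_len(dims[3])))
  ab <- b - a
  L2 <- sum(ab^2)
  tpar <- if (L2 == 0) rep(0, nrow(idx)) else
    pmin(pmax(((idx[, 1] - a[1]) * ab[1] + (idx[, 2] - a[2]) * ab[2] +
                 (idx[, 3] - a[3]) * ab[3]) / L2, 0), 1)
  d2 <- (idx[, 1] - (a[1] + tpar * ab[1]))^2 +
    (idx[, 2] - (a[2] + tpar * ab[2]))^2 +
    (idx[, 3] - (a[3] + tpar * ab[3]))^2
  arr[d2 <= radius^2] <- TRUE
  arr
}

# a small, well-separated ground-truth network with one cycle (beta1 = 1)
# for round-trip render -> segment -> graph tests
sparse_cycle_graph <- function() {
  nodes <- data.frame(
    id = 1:6,
    x_um = c(8, 28, 48, 48, 28, 8),
    y_um = c(8, 4, 8, 28, 32, 28),
    z_um = rep(4, 6))
  edges <- data.frame(from = c(1, 2, 3, 4, 5, 6),
                      to = c(2, 3, 4, 5, 6, 1))
  skeleton_graph(nodes, edges)
}

# brute-force optimal frame-to-frame assignment (oracle for the linker):
# max cardinality, then min total squared displacement, predictions =
# previous position + previous displacement
oracle_link <- function(frames, window = c(6, 6, 2)) {
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  n_tr <- nrow(frames[[1]])
  traj <- lapply(seq_len(n_tr), function(i)
    cbind(frame = 1, matrix(frames[[1]][i, ], nrow = 1)))
  for (f in 2:length(frames)) {
    pts <- frames[[f]]
    pred <- t(vapply(traj, function(m) {
      k <- nrow(m)
      if (k == 1) m[k, 2:4] else
        m[k, 2:4] + (m[k, 2:4] - m[k - 1, 2:4]) / (m[k, 1] - m[k - 1, 1]) *
          (f - m[k, 1])
    }, numeric(3)))
    nt <- length(traj); np <- nrow(pts)
    best <- NULL; best_card <- -1; best_cost <- Inf
    # enumerate assignments of tracks to points (or NA) via point orderings
    cand <- lapply(seq_len(nt), function(a) {
      ok <- abs(pts[, 1] - pred[a, 1]) <= window[1] &
        abs(pts[, 2] - pred[a, 2]) <= window[2] &
        abs(pts[, 3] - pred[a, 3]) <= window[3]
      which(ok)
    })
    assignments <- list(integer(0))
    for (a in seq_len(nt)) {
      nxt <- list()
      for (asn in assignments) {
        nxt[[length(nxt) + 1]] <- c(asn, NA_integer_)
        for (p in setdiff(cand[[a]], asn))
          nxt[[length(nxt) + 1]] <- c(asn, p)
      }
      assignments <- nxt
    }
    for (asn in assignments) {
      card <- sum(!is.na(asn))
      cost <- sum(vapply(which(!is.na(asn)), function(a)
        sum((pts[asn[a], ] - pred[a, ])^2), numeric(1)))
      if (card > best_card || (card == best_card && cost < best_cost)) {
        best <- asn; best_card <- card; best_cost <- cost
      }
    }
    for (a in seq_len(nt))
      if (!is.na(best[a]))
        traj[[a]] <- rbind(traj[[a]], c(f, pts[best[a], ]))
    for (p in setdiff(seq_len(np), best[!is.na(best)]))
      traj[[length(traj) + 1]] <- cbind(frame = f,
                                        matrix(pts[p, ], nrow = 1))
  }
  traj
}
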