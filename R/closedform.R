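#' Closed-form response to constant light
#'
#' Under constant irradiance the sensor signals are single exponentials and
#' the enforced position `p(t) = beta*(c1 - c2)` is a bi-exponential, so the
#' Kelvin-Voigt equation is solvable in closed form on every interval where
#' (a) the clipping state of `p` (below 0, between 0 and `x_max`, above
#' `x_max`) and (b) the response branch (`tau_kv` vs `tau_kv_star`) are
#' constant. The solution is a sum of exponentials in `tau1`, `tau2` and
#' the active mechanical time constant, with the degenerate `t*exp(-t/tau)`
#' form when time constants coincide. Interval boundaries (clip crossings
#' of the unimodal `p` and contraction/expansion switches) are located by
#' bracketed root-finding on the analytic expressions, and the state is
#' propagated exactly across them.
#'
#' @param I Constant irradiance (mW/cm^2).
#' @param params A [model_params()].
#' @param x0 Initial relative contraction.
#' @param c1_0,c2_0 Initial sensor signals; defaults are dark-adapted rest.
#' @param t Evaluation times (min, >= 0).
#' @return Numeric vector `x(t)`.
#' @export
constant_light_solution <- function(I, params, x0 = 0,
                                    c1_0 = 0, c2_0 = params$alpha2, t) {
  validate_model_params(params)
  if (length(I) != 1L || !is.finite(I) || I < 0)
    stop("I must be a single constant irradiance >= 0", call. = FALSE)
  if (any(t < -1e-12)) stop("evaluation times must be >= 0", call. = FALSE)
  t <- pmax(t, 0)
  T_max <- max(t, 1e-6)

  S1 <- params$alpha1 * I
  S2 <- params$alpha2 * as.numeric(I < params$i_th)
  P0 <- params$beta * (S1 - S2)
  P1 <- params$beta * (c1_0 - S1)
  P2 <- -params$beta * (c2_0 - S2)
  tau1 <- params$tau1; tau2 <- params$tau2
  p_raw <- function(u) P0 + P1 * exp(-u / tau1) + P2 * exp(-u / tau2)
  xmx <- params$x_max

  # clip-state crossings of the (unimodal) raw forcing with 0 and x_max
  grid <- seq(0, T_max, length.out = 1024L)
  crossings <- function(level) {
    g <- p_raw(grid) - level
    idx <- which(g[-1] * g[-length(g)] < 0)
    vapply(idx, function(i)
      stats::uniroot(function(u) p_raw(u) - level, c(grid[i], grid[i + 1]),
                     tol = 1e-12)$root, numeric(1))
  }
  events <- sort(unique(c(crossings(0), crossings(xmx), T_max)))
  events <- events[events > 1e-12]

  # analytic x on one interval: forcing q0 + q1 e^(-u/tau1) + q2 e^(-u/tau2)
  # (local u from interval start), branch time constant tau, start value xs
  make_seg <- function(q0, q1, q2, tau, xs) {
    deg1 <- abs(1 - tau / tau1) < 1e-9
    deg2 <- abs(1 - tau / tau2) < 1e-9
    g1 <- if (deg1) 0 else q1 / (1 - tau / tau1)
    g2 <- if (deg2) 0 else q2 / (1 - tau / tau2)
    h1 <- if (deg1) q1 / tau else 0
    h2 <- if (deg2) q2 / tau else 0
    cc <- xs - q0 - g1 - g2
    function(u)
      q0 + (g1 + h1 * u) * exp(-u / tau1) + (g2 + h2 * u) * exp(-u / tau2) +
        cc * exp(-u / tau)
  }

  segs_start <- numeric(0)
  segs_fun <- list()
  ts <- 0; xs <- min(max(x0, 0), xmx)
  guard <- 0L
  while (ts < T_max - 1e-12 && (guard <- guard + 1L) < 400L) {
    te <- min(events[events > ts + 1e-12], T_max)
    pr <- p_raw(ts + min(1e-9, (te - ts) / 2))
    if (pr < 0) { q0 <- 0; q1 <- 0; q2 <- 0 }
    else if (pr > xmx) { q0 <- xmx; q1 <- 0; q2 <- 0 }
    else { q0 <- P0; q1 <- P1 * exp(-ts / tau1); q2 <- P2 * exp(-ts / tau2) }
    f_at <- function(u) min(max(q0 + q1 * exp(-u / tau1) + q2 * exp(-u / tau2), 0), xmx)
    # branch from the sign of f - x just after ts; at contact use the
    # forcing trend
    dfs <- f_at(1e-7) - f_at(0)
    dir <- f_at(0) - xs
    if (abs(dir) < 1e-12) dir <- dfs
    tau <- if (dir >= 0) params$tau_kv else params$tau_kv_star
    xfun <- make_seg(q0, q1, q2, tau, xs)
    # earliest branch switch within (ts, te): sign change of f - x
    u_end <- te - ts
    ug <- seq(0, u_end, length.out = 256L)
    g <- q0 + q1 * exp(-ug / tau1) + q2 * exp(-ug / tau2) - xfun(ug)
    s0 <- sign(if (abs(g[1]) < 1e-12) dir else g[1])
    hit <- which(sign(g[-1]) * s0 < 0)
    if (length(hit) > 0) {
      i <- hit[1]
      u_sw <- tryCatch(
        stats::uniroot(function(u) q0 + q1 * exp(-u / tau1) +
                         q2 * exp(-u / tau2) - xfun(u),
                       c(max(ug[i] , 1e-12), ug[i + 1]), tol = 1e-12)$root,
        error = function(e) ug[i + 1])
      te <- ts + u_sw
    }
    segs_start <- c(segs_start, ts)
    segs_fun[[length(segs_fun) + 1L]] <- xfun
    xs <- min(max(xfun(te - ts), 0), xmx)
    ts <- te
  }
  if (length(segs_fun) == 0L) return(rep(min(max(x0, 0), xmx), length(t)))

  idx <- findInterval(t, segs_start)
  idx[idx < 1L] <- 1L
  x <- numeric(length(t))
  for (k in unique(idx)) {
    sel <- idx == k
    x[sel] <- segs_fun[[k]](t[sel] - segs_start[k])
  }
  pmin(pmax(x, 0), xmx)
}

#' Steady-state contraction under constant light
#'
#' The fixed point of the response: `min(beta*alpha1*I, x_max)` at or above
#' the repressor threshold, `max(0, min(beta*(alpha1*I - alpha2), x_max))`
#' below it, and 0 in prolonged darkness.
#'
#' @inheritParams constant_light_solution
#' @return The asymptotic relative contraction.
#' @export
steady_state_contraction <- function(I, params) {
  validate_model_params(params)
  s2 <- params$alpha2 * as.numeric(I < params$i_th)
  min(max(params$beta * (params$alpha1 * I - s2), 0), params$x_max)
}
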