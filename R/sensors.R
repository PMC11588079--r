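#' Photosensory signal dynamics under a light protocol
#'
#' Solves the two first-order signaling equations
#' `tau_i * dc_i/dt + c_i = s_i(I(t))` exactly on a piecewise-constant
#' protocol: within each segment the drive `s_i` is constant, so each signal
#' relaxes exponentially toward it, and segment boundaries propagate the
#' state. The avoidance drive is `s1 = alpha1 * I`; the repressor drive is
#' `s2 = alpha2` strictly below the threshold `i_th` and `0` at or above it.
#'
#' @param protocol A [light_protocol()].
#' @param params A [model_params()].
#' @param c1_0,c2_0 Initial signal levels (>= 0). The defaults are the
#'   dark-adapted rest state: `c1 = 0`, `c2 = alpha2`.
#' @param times Evaluation times (min); defaults to a dense grid over the
#'   protocol.
#' @return A data frame with columns `time_min`, `irradiance`, `c1`, `c2`.
#' @export
sensor_signals <- function(protocol, params, c1_0 = 0, c2_0 = params$alpha2,
                           times = NULL) {
  protocol <- as_light_protocol(protocol)
  validate_model_params(params)
  if (c1_0 < 0 || c2_0 < 0) stop("initial signals must be >= 0", call. = FALSE)
  if (is.null(times))
    times <- seq(protocol$t_start[1], protocol$t_end[nrow(protocol)],
                 by = min(params$tau1, params$tau2) / 50)
  if (any(diff(times) < 0)) stop("times must be non-decreasing", call. = FALSE)

  c1 <- numeric(length(times))
  c2 <- numeric(length(times))
  s1_of <- function(I) params$alpha1 * I
  s2_of <- function(I) params$alpha2 * as.numeric(I < params$i_th)

  # extend the last segment to cover any trailing query times
  segs <- protocol
  segs$t_end[nrow(segs)] <- max(segs$t_end[nrow(segs)], max(times))
  c1_a <- c1_0; c2_a <- c2_0
  for (k in seq_len(nrow(segs))) {
    a <- segs$t_start[k]; b <- segs$t_end[k]; I <- segs$irradiance[k]
    in_seg <- times >= a - 1e-12 & (times < b | k == nrow(segs))
    if (any(in_seg)) {
      dt <- times[in_seg] - a
      c1[in_seg] <- s1_of(I) + (c1_a - s1_of(I)) * exp(-dt / params$tau1)
      c2[in_seg] <- s2_of(I) + (c2_a - s2_of(I)) * exp(-dt / params$tau2)
    }
    d <- b - a
    c1_a <- s1_of(I) + (c1_a - s1_of(I)) * exp(-d / params$tau1)
    c2_a <- s2_of(I) + (c2_a - s2_of(I)) * exp(-d / params$tau2)
  }
  data.frame(time_min = times, irradiance = protocol_irradiance(protocol, times),
             c1 = c1, c2 = c2)
}

#' Enforced chloroplast position from the sensor signals
#'
#' The net signal sets the equilibrium position `p = beta * (c1 - c2)`,
#' clipped below at 0 (no negative contraction) and capped at `x_max`
#' (the cytoplasmic core bound).
#'
#' @param c1,c2 Signal levels on a common time grid.
#' @param params A [model_params()].
#' @return Numeric vector `p` with `0 <= p <= x_max`.
#' @export
forcing_position <- function(c1, c2, params) {
  validate_model_params(params)
  pmin(pmax(params$beta * (c1 - c2), 0), params$x_max)
}
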