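#' Piecewise-constant light stimulation protocol
#'
#' A protocol is an ordered set of contiguous, non-overlapping segments of
#' constant irradiance, e.g. alternating strong white light and dim red
#' imaging light.
#'
#' @param irradiance Irradiance of each segment (mW/cm^2, >= 0).
#' @param duration Duration of each segment (min, > 0); recycled against
#'   `irradiance`.
#' @param t0 Start time of the first segment (min).
#' @return A `light_protocol` object: a data frame with columns `t_start`,
#'   `t_end`, `irradiance`.
#' @examples
#' light_protocol(c(7.6, 0.4), c(2.5, 10))  # pulse then dim recovery
#' @export
light_protocol <- function(irradiance, duration, t0 = 0) {
  n <- max(length(irradiance), length(duration))
  irradiance <- rep_len(as.numeric(irradiance), n)
  duration <- rep_len(as.numeric(duration), n)
  if (any(!is.finite(irradiance)) || any(irradiance < 0))
    stop("irradiance must be finite and >= 0", call. = FALSE)
  if (any(!is.finite(duration)) || any(duration <= 0))
    stop("segment durations must be finite and > 0", call. = FALSE)
  t_end <- t0 + cumsum(duration)
  p <- data.frame(t_start = c(t0, t_end[-n]), t_end = t_end,
                  irradiance = irradiance)
  class(p) <- c("light_protocol", "data.frame")
  p
}

as_light_protocol <- function(x) {
  if (inherits(x, "light_protocol")) return(x)
  if (is.data.frame(x) && all(c("t_start", "t_end", "irradiance") %in% names(x))) {
    if (any(abs(x$t_start[-1] - x$t_end[-nrow(x)]) > 1e-9))
      stop("protocol segments must be contiguous", call. = FALSE)
    return(light_protocol(x$irradiance, x$t_end - x$t_start, t0 = x$t_start[1]))
  }
  stop("cannot interpret object as a light protocol", call. = FALSE)
}

#' Irradiance at given times
#'
#' Segments are right-open: a time exactly at a light switch takes the new
#' segment's irradiance; times past the last segment hold its level.
#'
#' @param protocol A [light_protocol()].
#' @param times Times (min).
#' @return Numeric vector of irradiances (mW/cm^2).
#' @export
protocol_irradiance <- function(protocol, times) {
  protocol <- as_light_protocol(protocol)
  idx <- findInterval(times, protocol$t_start)
  idx[idx < 1L] <- 1L
  protocol$irradiance[idx]
}

protocol_duration <- function(protocol) {
  protocol$t_end[nrow(protocol)] - protocol$t_start[1]
}

#' Read or write a light protocol as JSON
#'
#' @param protocol A [light_protocol()].
#' @param path File path.
#' @export
write_protocol <- function(protocol, path) {
  protocol <- as_light_protocol(protocol)
  jsonlite::write_json(as.data.frame(protocol), path, digits = NA)
  invisible(path)
}

#' @rdname write_protocol
#' @export
read_protocol <- function(path) {
  as_light_protocol(jsonlite::read_json(path, simplifyVector = TRUE))
}
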