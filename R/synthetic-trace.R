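#' Generate a noisy synthetic area/loss trace from the model
#'
#' Runs [simulate_response()], samples the relative area on a regular
#' output grid, and multiplies each sample by `(1 + eps)` with
#' `eps ~ N(0, noise_sd^2)` -- a multiplicative noise model matching the
#' dominant segmentation-noise source of measured area traces. The loss
#' ratio column is filled under the opaque-chloroplast assumption
#' (`loss_ratio = relative_area`).
#'
#' @param params A [model_params()].
#' @param protocol A [light_protocol()].
#' @param noise_sd Multiplicative noise SD (0 = noiseless).
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @param out_dt Output sampling interval (min).
#' @param x0,c1_0,c2_0 Initial state passed to [simulate_response()].
#' @return An `area_loss_trace` data frame with columns `time_min`,
#'   `irradiance_mW_cm2`, `relative_area`, `loss_ratio`.
#' @export
simulate_area_trace <- function(params, protocol, noise_sd = 0.05,
                                seed = NULL, out_dt = 0.5,
                                x0 = 0, c1_0 = 0, c2_0 = params$alpha2) {
  if (!is.null(seed)) set.seed(seed)
  protocol <- as_light_protocol(protocol)
  sim <- simulate_response(protocol, params, x0 = x0, c1_0 = c1_0, c2_0 = c2_0)
  t_out <- seq(protocol$t_start[1], protocol$t_end[nrow(protocol)], by = out_dt)
  a <- stats::approx(sim$time_min, sim$relative_area, xout = t_out, rule = 2)$y
  if (noise_sd > 0) a <- a * (1 + stats::rnorm(length(a), 0, noise_sd))
  out <- data.frame(time_min = t_out,
                    irradiance_mW_cm2 = protocol_irradiance(protocol, t_out),
                    relative_area = a, loss_ratio = a)
  class(out) <- c("area_loss_trace", "data.frame")
  out
}

#' Read or write an area/loss trace as CSV
#'
#' The on-disk schema is `time_min, irradiance_mW_cm2, relative_area,
#' loss_ratio`.
#'
#' @param trace An `area_loss_trace` data frame.
#' @param path File path.
#' @export
write_trace_csv <- function(trace, path) {
  need <- c("time_min", "irradiance_mW_cm2", "relative_area", "loss_ratio")
  miss <- setdiff(need, names(trace))
  if (length(miss) > 0)
    stop("trace is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  utils::write.csv(as.data.frame(trace)[need], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  tr <- utils::read.csv(path)
  need <- c("time_min", "relative_area")
  miss <- setdiff(need, names(tr))
  if (length(miss) > 0)
    stop("trace CSV ", path, " is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (is.null(tr$irradiance_mW_cm2)) tr$irradiance_mW_cm2 <- NA_real_
  if (is.null(tr$loss_ratio)) tr$loss_ratio <- NA_real_
  class(tr) <- c("area_loss_trace", "data.frame")
  tr
}
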