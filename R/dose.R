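#' Maximal relative area decrease of a trace
#'
#' `delta_A_max = 1 - min_t A(t)/A0` for a relative-area trace normalized
#' to its initial area.
#'
#' @param trace A `response_trace`/`area_loss_trace` data frame with a
#'   `relative_area` column, or a bare numeric vector of `A(t)/A0`.
#' @return The maximal relative area decrease in `[0, 1]`.
#' @export
max_contraction <- function(trace) {
  a <- if (is.data.frame(trace)) trace$relative_area else as.numeric(trace)
  if (is.null(a) || length(a) == 0L || all(is.na(a)))
    stop("trace has no relative_area values", call. = FALSE)
  1 - min(a, na.rm = TRUE)
}

#' Dose-response of maximal contraction versus irradiance
#'
#' Computes the per-trace maximal area decrease ([max_contraction()]) and
#' its Pearson correlation with the stimulation irradiance.
#'
#' @param traces List of relative-area traces (data frames or vectors).
#' @param irradiances Irradiance per trace (mW/cm^2), same length.
#' @return A list of class `dose_response` with `irradiances`,
#'   `delta_a_max` and `pearson_rho`.
#' @export
dose_response <- function(traces, irradiances) {
  if (!is.list(traces)) traces <- list(traces)
  if (length(traces) != length(irradiances))
    stop("traces and irradiances must have equal length", call. = FALSE)
  if (length(traces) < 3L)
    stop("need at least 3 traces for a dose-response", call. = FALSE)
  d <- vapply(traces, max_contraction, numeric(1))
  if (stats::sd(d) == 0 || stats::sd(irradiances) == 0)
    stop("zero-variance input: correlation undefined", call. = FALSE)
  structure(list(irradiances = irradiances, delta_a_max = d,
                 pearson_rho = stats::cor(irradiances, d)),
            class = "dose_response")
}

#' Order-of-magnitude diffusion coefficient of the triggering signal
#'
#' A light stimulus on one side of the cell triggers a response across the
#' whole cell length `L` within a time `tau`, implying a signaling species
#' with diffusion coefficient `D = L^2 / tau`.
#'
#' @param L Cell length (um, > 0).
#' @param tau Signal propagation time (s, > 0).
#' @return A list with `cell_length_um`, `signal_time_s` and
#'   `diffusion_um2_s` (`= L^2/tau`, exactly).
#' @examples
#' estimate_signal_diffusion(80, 40)$diffusion_um2_s   # 160
#' estimate_signal_diffusion(100, 20)$diffusion_um2_s  # 500
#' @export
estimate_signal_diffusion <- function(L, tau) {
  if (any(L <= 0) || any(tau <= 0))
    stop("L and tau must be > 0", call. = FALSE)
  list(cell_length_um = L, signal_time_s = tau, diffusion_um2_s = L^2 / tau)
}
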