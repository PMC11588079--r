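#' Low-pass gain of the light-to-area cascade
#'
#' In the strong-light branch (repressor inactive) the light signal passes
#' through two first-order stages in series -- the avoidance sensor
#' (`tau1`) and the Kelvin-Voigt element (`tau_kv`) -- so the DC-normalized
#' magnitude response is
#' `|H(omega)| = [(1 + omega^2 tau1^2) (1 + omega^2 tau_kv^2)]^(-1/2)`,
#' a Butterworth-like two-pole low-pass: slow light fluctuations are
#' followed, fast flicker is ignored.
#'
#' @param omega Angular frequency (min^-1, >= 0); vectorized.
#' @param params A [model_params()].
#' @return Gain `|H(omega)|` in `[0, 1]`, equal to 1 at `omega = 0`.
#' @export
transfer_magnitude <- function(omega, params) {
  validate_model_params(params)
  if (any(omega < 0)) stop("omega must be >= 0", call. = FALSE)
  1 / sqrt((1 + omega^2 * params$tau1^2) * (1 + omega^2 * params$tau_kv^2))
}

#' Half-power cutoff frequency of the light response
#'
#' The angular frequency at which the squared gain of
#' [transfer_magnitude()] falls to one half (-3 dB). Unique because the
#' gain decreases monotonically; found by bracketed root-finding.
#'
#' @param params A [model_params()].
#' @return Cutoff `omega_c` (min^-1).
#' @examples
#' cutoff_frequency(lunula_params())  # ~0.32 min^-1
#' @export
cutoff_frequency <- function(params) {
  validate_model_params(params)
  f <- function(w) transfer_magnitude(w, params)^2 - 0.5
  hi <- 1 / min(params$tau1, params$tau_kv)
  while (f(hi) > 0) hi <- hi * 2
  stats::uniroot(f, c(0, hi), tol = 1e-12)$root
}
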