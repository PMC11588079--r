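#' Parameters of the two-sensor viscoelastic light-response model
#'
#' The chloroplast's relative contraction `x(t)` (projected area
#' `A(t)/A0 = 1 - x(t)`) relaxes, as a Kelvin-Voigt element, toward an
#' enforced position `p(t) = beta * (c1(t) - c2(t))` set by two first-order
#' photosensory signals: an avoidance sensor `c1` driven by
#' `s1(I) = alpha1 * I` at all irradiances, and a repressor `c2` driven by
#' `s2(I) = alpha2 * H(i_th - I)` that is active only below the threshold
#' irradiance `i_th` (with `H(I >= i_th) = 0` and `H(I < i_th) = 1`).
#' Contraction (`dx/dt > 0`) relaxes with time constant `tau_kv`, expansion
#' (`dx/dt < 0`) with the slower `tau_kv_star`.
#'
#' @param tau_kv Contraction response time (min).
#' @param tau_kv_star Expansion response time (min).
#' @param tau1 Avoidance-sensor signaling time (min).
#' @param tau2 Repressor-sensor signaling time (min).
#' @param alpha1 Avoidance gain, signal per irradiance ((mW/cm^2)^-1).
#' @param alpha2 Repressor signal amplitude (dimensionless).
#' @param beta Enforced extension per unit net signal (dimensionless).
#' @param i_th Repressor threshold irradiance (mW/cm^2).
#' @param x_max Cap on relative contraction, set by the cytoplasmic core
#'   area: the projected area cannot drop below `1 - x_max`.
#' @return An object of class `model_params` (a validated named list).
#' @seealso [lunula_params()] for the population-mean parameter set used as
#'   the package default.
#' @export
model_params <- function(tau_kv = 2.25, tau_kv_star = 7.2,
                         tau1 = 1.74, tau2 = 1.76,
                         alpha1 = 1 / 30, alpha2 = 0.08, beta = 1,
                         i_th = 2.8, x_max = 0.4) {
  p <- list(tau_kv = tau_kv, tau_kv_star = tau_kv_star,
            tau1 = tau1, tau2 = tau2,
            alpha1 = alpha1, alpha2 = alpha2, beta = beta,
            i_th = i_th, x_max = x_max)
  validate_model_params(p)
  class(p) <- "model_params"
  p
}

validate_model_params <- function(p) {
  num1 <- function(v) is.numeric(v) && length(v) == 1L && is.finite(v)
  for (nm in c("tau_kv", "tau_kv_star", "tau1", "tau2"))
    if (!num1(p[[nm]]) || p[[nm]] <= 0)
      stop("model parameter '", nm, "' must be a positive time constant (min)",
           call. = FALSE)
  for (nm in c("alpha1", "alpha2", "beta"))
    if (!num1(p[[nm]]) || p[[nm]] < 0)
      stop("model parameter '", nm, "' must be >= 0", call. = FALSE)
  if (!num1(p$i_th) || p$i_th <= 0)
    stop("model parameter 'i_th' must be > 0", call. = FALSE)
  if (!num1(p$x_max) || p$x_max <= 0 || p$x_max > 1)
    stop("model parameter 'x_max' must lie in (0, 1]", call. = FALSE)
  invisible(p)
}

#' Population-mean fitted parameter set
#'
#' The mean fitted time constants for light-driven chloroplast contraction
#' in *P. lunula*: `tau_kv` = 2.25 min, `tau_kv_star` = 7.2 min,
#' `tau1` = 1.74 min, `tau2` = 1.76 min, together with the package's
#' calibrated sensory gains (see the methods vignette for how `alpha1`,
#' `alpha2`, `beta` and `i_th` were chosen).
#'
#' @return A `model_params` object.
#' @export
lunula_params <- function() model_params()

#' Reported spread of the fitted time constants
#'
#' One standard deviation of the per-cell fitted values around the
#' population means of [lunula_params()], with the number of fitted cells.
#'
#' @return A data frame with columns `param`, `mean`, `sd`, `n`.
#' @export
lunula_param_spread <- function() {
  data.frame(
    param = c("tau_kv", "tau_kv_star", "tau1", "tau2"),
    mean = c(2.25, 7.2, 1.74, 1.76),
    sd = c(0.8, 0.7, 0.8, 0.3),
    n = c(42L, 6L, 42L, 6L),
    stringsAsFactors = FALSE
  )
}

#' @export
print.model_params <- function(x, ...) {
  cat("Two-sensor Kelvin-Voigt light-response parameters\n")
  cat(sprintf("  tau_kv  %6.3f min   tau_kv* %6.3f min\n", x$tau_kv, x$tau_kv_star))
  cat(sprintf("  tau1    %6.3f min   tau2    %6.3f min\n", x$tau1, x$tau2))
  cat(sprintf("  alpha1  %6.4f (mW/cm2)^-1   alpha2 %6.4f   beta %6.3f\n",
              x$alpha1, x$alpha2, x$beta))
  cat(sprintf("  i_th    %6.3f mW/cm2       x_max  %6.3f\n", x$i_th, x$x_max))
  invisible(x)
}

#' Read or write model parameters as JSON
#'
#' @param params A `model_params` object.
#' @param path File path.
#' @return `write_params()` returns `path` invisibly; `read_params()`
#'   returns a `model_params` object.
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "model_params"))
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  do.call(model_params, jsonlite::read_json(path, simplifyVector = TRUE))
}
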