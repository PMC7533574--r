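# The fractional motion (FM) forward signal model.
#
# The FM framework describes water displacement as an H-self-similar process
# with alpha-stable, stationary increments. Its diffusion-weighted signal is
#
#   S/S0 = exp(-eta * D * gamma^alpha * G0^alpha * Delta^(alpha + alpha*H))
#
# where alpha is the Noah exponent (alpha = 2: Gaussian increments;
# 0 < alpha < 2: Levy increments), H the Hurst exponent, D the anomalous
# diffusion coefficient, and eta a dimensionless factor set by alpha, H,
# delta and Delta. The memory parameter mu = H - 1/alpha summarises increment
# correlation (mu < 0: anti-persistent, mu > 0: persistent).
#
# D is carried in millimetre-based units (mm^alpha s^(-alpha*H)); at
# alpha = 2, H = 1/2 it coincides with an ADC in mm^2/s under the
# narrow-pulse b-value gamma^2 G0^2 delta^2 Delta.

.check_fm_params <- function(alpha, hurst, D = NULL) {
  if (any(!is.finite(alpha)) || any(alpha <= 0) || any(alpha > 2))
    stop("alpha must lie in (0, 2]")
  if (any(!is.finite(hurst)) || any(hurst <= 0) || any(hurst >= 1))
    stop("hurst must lie in (0, 1)")
  if (!is.null(D) && (any(!is.finite(D)) || any(D < 0)))
    stop("D must be non-negative and finite")
  invisible(TRUE)
}

#' FM parameter triple
#'
#' Bundles one voxel's (or subject's) anomalous diffusion state: the
#' diffusion coefficient `D`, the Noah exponent `alpha` and the Hurst
#' exponent `hurst`, with the derived memory parameter `mu`.
#'
#' @param D anomalous diffusion coefficient, mm^alpha s^(-alpha*H).
#' @param alpha Noah exponent, in (0, 2].
#' @param hurst Hurst exponent, in (0, 1).
#' @return an object of class `fm_params`.
#' @export
fm_params <- function(D, alpha, hurst) {
  .check_fm_params(alpha, hurst, D)
  structure(list(D = D, alpha = alpha, hurst = hurst,
                 mu = memory_parameter(alpha, hurst)),
            class = "fm_params")
}

#' @export
print.fm_params <- function(x, ...) {
  cat(sprintf("<fm_params> D = %.4g, alpha = %.4g, H = %.4g (mu = %.4g)\n",
              x$D, x$alpha, x$hurst, x$mu))
  invisible(x)
}

#' Memory parameter
#'
#' mu = H - 1/alpha. Negative values indicate anti-persistent (short-memory)
#' increments, positive values persistent (long-memory) increments; the
#' Brownian case (alpha = 2, H = 1/2) gives mu = 0.
#'
#' @param alpha Noah exponent(s), > 0.
#' @param hurst Hurst exponent(s).
#' @return mu, dimensionless.
#' @examples
#' memory_parameter(1.588, 0.464)  # -0.166 at 3 decimals
#' @export
memory_parameter <- function(alpha, hurst) {
  if (any(!is.finite(alpha)) || any(alpha <= 0)) stop("alpha must be positive")
  hurst - 1 / alpha
}

#' Dimensionless pulse-timing factor eta
#'
#' The factor that absorbs the gradient pulse timing into the FM signal
#' exponent. The default `"narrow_pulse"` strategy uses the factorisation
#' eta = (delta/Delta)^alpha, under which the exponent reduces to
#' D gamma^alpha G0^alpha delta^alpha Delta^(alpha*H) and the Gaussian case
#' (alpha = 2, H = 1/2) recovers the mono-exponential model exactly with
#' b = gamma^2 G0^2 delta^2 Delta. Alternative finite-pulse expressions can
#' be registered as strategies without touching callers; fitted D values are
#' comparable only within one eta convention (alpha, H and mu are not
#' affected by the choice within this family).
#'
#' @param alpha Noah exponent, in (0, 2].
#' @param hurst Hurst exponent, in (0, 1). Unused by the default strategy but
#'   part of the strategy signature.
#' @param delta gradient pulse duration, s.
#' @param Delta gradient separation time, s; `delta <= Delta`.
#' @param model strategy name; `"narrow_pulse"` is the only built-in.
#' @return eta > 0, dimensionless.
#' @export
compute_eta <- function(alpha, hurst, delta, Delta, model = "narrow_pulse") {
  .check_fm_params(alpha, hurst)
  if (any(!is.finite(delta)) || any(delta <= 0) || any(!is.finite(Delta)) ||
      any(Delta <= 0) || any(delta > Delta))
    stop("need 0 < delta <= Delta")
  eta_fn <- .eta_strategies[[model]]
  if (is.null(eta_fn)) stop("unknown eta model: ", model)
  eta_fn(alpha, hurst, delta, Delta)
}

.eta_strategies <- list(
  narrow_pulse = function(alpha, hurst, delta, Delta) (delta / Delta)^alpha
)

# Log of the unit-D signal exponent for each weighted measurement:
# exponent = D * exp(alpha*log(gamma_mm*G0*delta) + alpha*H*log(Delta)),
# where gamma_mm = gamma*1e-3 converts gamma*G0 from 1/(m s) to 1/(mm s) so
# that D is in millimetre units. Valid for the narrow-pulse eta family.
.fm_log_unit_exponent <- function(scheme, Delta = NULL, G0 = NULL,
                                  eta_model = "narrow_pulse") {
  if (!identical(eta_model, "narrow_pulse"))
    stop("log-space exponent only available for the narrow_pulse eta family")
  if (is.null(Delta)) {
    Delta <- scheme$measurements$Delta
    G0 <- scheme$measurements$G0
  }
  list(a = log(scheme$gamma * 1e-3 * G0 * scheme$delta), b = log(Delta))
}

#' FM forward signal
#'
#' Evaluates the FM signal decay over the weighted measurements of an
#' acquisition scheme. The model is isotropic: the three gradient directions
#' of one (Delta, G0) cell receive identical signals. The exponent is
#' computed in log space to remain stable at extreme alpha, H.
#'
#' @param params an [fm_params()] object (or list with `D`, `alpha`, `hurst`).
#' @param scheme an `fm_scheme`.
#' @param S0 unweighted signal amplitude, > 0.
#' @param eta_model eta strategy passed to [compute_eta()].
#' @return numeric vector of signals, one per weighted measurement, in
#'   scheme order; all values in (0, S0].
#' @export
fm_signal <- function(params, scheme, S0 = 1, eta_model = "narrow_pulse") {
  stopifnot(inherits(scheme, "fm_scheme"))
  .check_fm_params(params$alpha, params$hurst, params$D)
  if (!is.finite(S0) || S0 <= 0) stop("S0 must be positive")
  S0 * fm_attenuation(params$D, params$alpha, params$hurst, scheme,
                      eta_model = eta_model)
}

#' FM attenuation S/S0 over a scheme's measurements
#'
#' Vectorised core of [fm_signal()]; exposed for fitting and simulation.
#'
#' @inheritParams fm_signal
#' @param D,alpha,hurst scalar FM parameters.
#' @param cells optional data.frame with `Delta` and `G0` columns to evaluate
#'   on (defaults to all weighted measurements of `scheme`).
#' @return attenuation values in (0, 1].
#' @export
fm_attenuation <- function(D, alpha, hurst, scheme, cells = NULL,
                           eta_model = "narrow_pulse") {
  if (identical(eta_model, "narrow_pulse")) {
    lu <- .fm_log_unit_exponent(scheme, Delta = cells$Delta, G0 = cells$G0)
    exp(-D * exp(alpha * lu$a + alpha * hurst * lu$b))
  } else {
    if (is.null(cells)) cells <- scheme$measurements
    eta <- compute_eta(alpha, hurst, scheme$delta, cells$Delta, model = eta_model)
    g_mm <- scheme$gamma * 1e-3
    exp(-eta * D * (g_mm * cells$G0)^alpha * cells$Delta^(alpha + alpha * hurst))
  }
}

#' Mono-exponential (ADC) signal model
#'
#' The conventional diffusion model S = S0 exp(-b ADC), kept as the
#' comparison model for the FM fit.
#'
#' @param adc apparent diffusion coefficient, mm^2/s, >= 0.
#' @param b b-value(s), s/mm^2, >= 0.
#' @param S0 unweighted amplitude, > 0.
#' @return signal amplitude(s).
#' @export
mono_exp_signal <- function(adc, b, S0 = 1) {
  if (any(!is.finite(adc)) || any(adc < 0)) stop("adc must be non-negative")
  if (any(!is.finite(b)) || any(b < 0)) stop("b must be non-negative")
  if (!is.finite(S0) || S0 <= 0) stop("S0 must be positive")
  S0 * exp(-b * adc)
}
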