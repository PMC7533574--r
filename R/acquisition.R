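# Multi-(Delta, G0) pulsed-gradient spin-echo acquisition schemes.
#
# Interface units follow acquisition-console convention (ms, mT/m); all
# internal fields are SI (s, T/m). b-values are reported in s/mm^2.

#' Proton gyromagnetic ratio
#'
#' Default gyromagnetic ratio of the proton, in rad s^-1 T^-1.
#' @export
GAMMA_PROTON <- 2.6752218744e8

#' Stejskal-Tanner b-value
#'
#' Computes the diffusion weighting of a pulsed-gradient spin-echo
#' measurement, b = gamma^2 G0^2 delta^2 (Delta - delta/3), converted to
#' s/mm^2. Full precision is retained; round only for display.
#'
#' @param gamma gyromagnetic ratio, rad s^-1 T^-1.
#' @param G0 diffusion gradient amplitude, T/m. May be a vector; zero allowed
#'   (b = 0).
#' @param delta gradient pulse duration, s.
#' @param Delta gradient separation time, s. Vectorised with `G0`.
#' @return b-value(s) in s/mm^2.
#' @examples
#' compute_bvalue(GAMMA_PROTON, 39.01e-3, 20.676e-3, 27.060e-3)  # ~939
#' @export
compute_bvalue <- function(gamma, G0, delta, Delta) {
  stopifnot(is.numeric(gamma), is.numeric(G0), is.numeric(delta), is.numeric(Delta))
  if (!all(is.finite(gamma)) || !all(is.finite(G0)) ||
      !all(is.finite(delta)) || !all(is.finite(Delta)))
    stop("all inputs must be finite")
  if (any(gamma <= 0) || any(delta <= 0) || any(Delta <= 0))
    stop("gamma, delta and Delta must be positive")
  if (any(G0 < 0)) stop("G0 must be non-negative")
  if (any(delta > Delta)) stop("delta must not exceed Delta")
  gamma^2 * G0^2 * delta^2 * (Delta - delta / 3) * 1e-6
}

#' Log-spaced gradient amplitude table
#'
#' Returns `n` gradient amplitudes geometrically spaced from `gmin` to `gmax`
#' inclusive, i.e. evenly spaced on the log axis, as used to spread b-values
#' over the attenuation curve.
#'
#' @param gmin,gmax smallest and largest amplitude (same units in as out).
#' @param n number of amplitudes, at least 2.
#' @return numeric vector of length `n` with constant consecutive ratio.
#' @export
make_gradient_amplitudes <- function(gmin, gmax, n) {
  stopifnot(is.numeric(gmin), is.numeric(gmax), length(gmin) == 1, length(gmax) == 1)
  if (!is.finite(gmin) || !is.finite(gmax) || gmin <= 0 || gmin >= gmax)
    stop("need 0 < gmin < gmax")
  if (!is.numeric(n) || length(n) != 1 || n < 2 || n != round(n))
    stop("n must be an integer >= 2")
  exp(seq(log(gmin), log(gmax), length.out = n))
}

#' Build a multi-(Delta, G0) acquisition scheme
#'
#' Constructs the full measurement table of a pulsed-gradient spin-echo
#' protocol: one weighted measurement per (Delta, G0, direction) triple, with
#' b-values derived by [compute_bvalue()], preceded conceptually by `n_b0`
#' unweighted (b = 0) volumes. Volume order in any matching 4D series is:
#' all b0 volumes first, then weighted volumes grouped by Delta (in the
#' given order), G0 ascending within Delta, and direction x, y, z within G0.
#'
#' @param Deltas gradient separation times, seconds.
#' @param G0s gradient amplitudes, T/m.
#' @param delta gradient pulse duration, seconds; must not exceed any Delta.
#' @param n_b0 number of b = 0 volumes (>= 1; required for normalisation).
#' @param directions subset of c("x", "y", "z").
#' @param gamma gyromagnetic ratio, rad s^-1 T^-1.
#' @return an object of class `fm_scheme`: a list with elements `gamma`,
#'   `delta`, `n_b0` and `measurements`, a data.frame with columns
#'   `Delta` (s), `G0` (T/m), `direction`, `bvalue` (s/mm^2).
#' @examples
#' sch <- default_scheme()
#' length(unique(round(sch$measurements$bvalue)))  # 18 distinct b-values
#' @export
build_scheme <- function(Deltas, G0s, delta, n_b0 = 1,
                         directions = c("x", "y", "z"),
                         gamma = GAMMA_PROTON) {
  if (length(Deltas) == 0 || length(G0s) == 0 || length(directions) == 0)
    stop("Deltas, G0s and directions must be non-empty")
  if (!all(directions %in% c("x", "y", "z")) || anyDuplicated(directions))
    stop("directions must be a subset of c('x','y','z') without duplicates")
  if (any(!is.finite(Deltas)) || any(Deltas <= 0)) stop("Deltas must be positive")
  if (any(!is.finite(G0s)) || any(G0s <= 0)) stop("G0s must be positive")
  if (!is.finite(delta) || delta <= 0) stop("delta must be positive")
  if (delta > min(Deltas)) stop("delta must not exceed the smallest Delta")
  if (n_b0 < 1) stop("n_b0 must be at least 1")
  G0s <- sort(G0s)
  directions <- c("x", "y", "z")[c("x", "y", "z") %in% directions]
  grid <- expand.grid(direction = directions, G0 = G0s, Delta = Deltas,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  # expand.grid varies the first factor fastest, giving the documented order
  meas <- data.frame(
    Delta = grid$Delta,
    G0 = grid$G0,
    direction = grid$direction,
    bvalue = compute_bvalue(gamma, grid$G0, delta, grid$Delta),
    stringsAsFactors = FALSE
  )
  structure(
    list(gamma = gamma, delta = delta, n_b0 = as.integer(n_b0),
         measurements = meas),
    class = "fm_scheme"
  )
}

#' The 18-b-value hippocampal protocol
#'
#' The default acquisition: Delta arrayed at 27.060, 39.560 and 52.060 ms;
#' six gradient amplitudes geometrically spaced from 15.67 to 49.00 mT/m;
#' delta fixed at 20.676 ms; three orthogonal directions; 12 b = 0 volumes.
#' This yields 18 distinct non-zero b-values from about 151 to 3317 s/mm^2,
#' each repeated along x, y and z.
#'
#' @param gamma gyromagnetic ratio, rad s^-1 T^-1.
#' @return an `fm_scheme` object.
#' @export
default_scheme <- function(gamma = GAMMA_PROTON) {
  build_scheme(
    Deltas = c(27.060, 39.560, 52.060) * 1e-3,
    G0s = make_gradient_amplitudes(15.67e-3, 49.00e-3, 6),
    delta = 20.676e-3,
    n_b0 = 12,
    directions = c("x", "y", "z"),
    gamma = gamma
  )
}

#' @export
print.fm_scheme <- function(x, ...) {
  nb <- length(unique(signif(scheme_cells(x)$bvalue, 10)))
  cat(sprintf(
    "<fm_scheme> %d weighted volumes (%d distinct b), %d b0 volumes\n",
    nrow(x$measurements), nb, x$n_b0))
  cat(sprintf("  gamma = %.6g rad/s/T, delta = %.4g ms\n",
              x$gamma, x$delta * 1e3))
  cat(sprintf("  b range: %.0f - %.0f s/mm^2\n",
              min(x$measurements$bvalue), max(x$measurements$bvalue)))
  invisible(x)
}

#' Distinct (Delta, G0) cells of a scheme
#'
#' One row per (Delta, G0) combination, i.e. per distinct b-value, collapsing
#' the gradient directions. Row order follows the measurement order.
#'
#' @param scheme an `fm_scheme`.
#' @return data.frame with columns `Delta`, `G0`, `bvalue`, `n_dir`.
#' @export
scheme_cells <- function(scheme) {
  stopifnot(inherits(scheme, "fm_scheme"))
  m <- scheme$measurements
  key <- paste(format(m$Delta, digits = 15), format(m$G0, digits = 15))
  first <- !duplicated(key)
  cells <- m[first, c("Delta", "G0", "bvalue")]
  cells$n_dir <- as.integer(table(key)[key[first]])
  rownames(cells) <- NULL
  cells
}

#' Total volume count implied by a scheme
#' @param scheme an `fm_scheme`.
#' @return integer: `n_b0` plus the number of weighted measurements.
#' @export
scheme_n_volumes <- function(scheme) {
  stopifnot(inherits(scheme, "fm_scheme"))
  scheme$n_b0 + nrow(scheme$measurements)
}
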