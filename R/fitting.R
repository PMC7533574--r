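# Voxelwise estimation of FM parameters and ADC.
#
# Fitting operates on direction-averaged normalised signals: S0 is fixed
# from the mean of the b0 volumes (not a free parameter), and the three
# orthogonal directions of each (Delta, G0) cell are combined by the
# geometric mean of S/S0 — equivalent to arithmetically averaging the
# log-attenuations, which suppresses diffusion anisotropy. The FM fit then
# minimises sum((model - observed)^2) in the attenuation domain over
# (D, alpha, H) with box bounds, multi-started from a coarse (alpha, H)
# grid with D seeded from a Gaussian-limit log-linear fit.

#' Default fitting configuration
#'
#' @param bounds named list with two-element vectors `D`, `alpha`, `hurst`.
#'   Defaults: D in \[1e-8, 10\] (model units), alpha in \[0.5, 2\], H in
#'   \[0.05, 0.95\] — broader than any value observed in healthy or AD
#'   hippocampus, while keeping exponents numerically stable.
#' @param init_alpha,init_hurst multi-start grid values.
#' @param ftol convergence tolerance on the cost.
#' @param maxiter iteration cap per start.
#' @param eta_model eta strategy (see [compute_eta()]).
#' @param direction_average `"geometric"` (default) or `"arithmetic"`.
#' @param adc_b_target target b-value (s/mm^2) for the two-point ADC; the
#'   weighted cell whose b is nearest the target is used (ties towards the
#'   lower b), with that cell's actual b in the formula.
#' @return a list of class `fm_fit_config`.
#' @export
fm_fit_config <- function(bounds = list(D = c(1e-8, 10),
                                        alpha = c(0.5, 2.0),
                                        hurst = c(0.05, 0.95)),
                          init_alpha = c(1.0, 1.5, 2.0),
                          init_hurst = c(0.3, 0.5, 0.7),
                          ftol = 1e-10,
                          maxiter = 1000,
                          eta_model = "narrow_pulse",
                          direction_average = c("geometric", "arithmetic"),
                          adc_b_target = 954) {
  direction_average <- match.arg(direction_average)
  structure(list(bounds = bounds, init_alpha = init_alpha,
                 init_hurst = init_hurst, ftol = ftol, maxiter = maxiter,
                 eta_model = eta_model, direction_average = direction_average,
                 adc_b_target = adc_b_target),
            class = "fm_fit_config")
}

#' Normalise a 4D series and average over directions
#'
#' Per voxel: S0 is the arithmetic mean of the b0 volumes; each (Delta, G0)
#' cell's attenuation is the geometric mean over its gradient directions of
#' S/S0 (configurable to arithmetic). Attenuations are clipped to
#' \[1e-6, Inf) before any log operation.
#'
#' @param dwi4d 4D array (x, y, z, volume) whose 4th extent equals
#'   `scheme_n_volumes(scheme)`, ordered b0-first as the scheme documents.
#' @param scheme an `fm_scheme`.
#' @param mask optional 3D logical array restricting computation.
#' @param config an [fm_fit_config()].
#' @return list with `cells` (the scheme's distinct (Delta, G0) cells),
#'   `S0` (3D array), `attenuation` (matrix: one row per masked voxel, one
#'   column per cell), `voxels` (matrix of voxel indices), and `unfittable`
#'   (logical per masked voxel: S0 <= 0).
#' @export
normalize_and_average <- function(dwi4d, scheme, mask = NULL,
                                  config = fm_fit_config()) {
  stopifnot(inherits(scheme, "fm_scheme"), length(dim(dwi4d)) == 4)
  nvol <- scheme_n_volumes(scheme)
  if (dim(dwi4d)[4] != nvol)
    stop(sprintf("4th dimension (%d) does not match scheme volume count (%d)",
                 dim(dwi4d)[4], nvol))
  spat <- dim(dwi4d)[1:3]
  if (is.null(mask)) mask <- array(TRUE, spat)
  if (!identical(dim(mask), spat)) stop("mask shape does not match volume")
  vox <- which(array(as.logical(mask), spat))
  nv <- prod(spat)
  mat <- matrix(dwi4d, nrow = nv)[vox, , drop = FALSE]

  b0 <- mat[, seq_len(scheme$n_b0), drop = FALSE]
  S0v <- rowMeans(b0)
  unfittable <- !is.finite(S0v) | S0v <= 0

  m <- scheme$measurements
  key <- paste(format(m$Delta, digits = 15), format(m$G0, digits = 15))
  cells <- scheme_cells(scheme)
  cell_idx <- match(key, paste(format(cells$Delta, digits = 15),
                               format(cells$G0, digits = 15)))
  w <- mat[, scheme$n_b0 + seq_len(nrow(m)), drop = FALSE]
  att_meas <- pmax(w / ifelse(unfittable, NA_real_, S0v), 1e-6)

  att <- matrix(NA_real_, nrow = length(vox), ncol = nrow(cells))
  for (ci in seq_len(nrow(cells))) {
    cols <- which(cell_idx == ci)
    att[, ci] <- if (config$direction_average == "geometric")
      exp(rowMeans(log(att_meas[, cols, drop = FALSE])))
    else
      rowMeans(att_meas[, cols, drop = FALSE])
  }

  S0arr <- array(NA_real_, spat)
  S0arr[vox] <- S0v
  list(cells = cells, S0 = S0arr, attenuation = att,
       voxels = arrayInd(vox, spat), voxel_index = vox,
       unfittable = unfittable)
}

# residual and analytic jacobian of the attenuation model, parameterised as
# p = (D, alpha, H); a = log(gamma_mm G0 delta), b = log(Delta) per cell.
.fm_residual <- function(p, a, b, obs) {
  E <- p[1] * exp(p[2] * a + p[2] * p[3] * b)
  exp(-E) - obs
}

.fm_jacobian <- function(p, a, b, obs) {
  E <- p[1] * exp(p[2] * a + p[2] * p[3] * b)
  mE <- exp(-E)
  cbind(-mE * E / p[1],
        -mE * E * (a + p[3] * b),
        -mE * E * p[2] * b)
}

#' Fit the FM model in one voxel
#'
#' Bounded nonlinear least squares on normalised, direction-averaged
#' attenuations: minimises the attenuation-domain sum of squares over
#' (D, alpha, H) within the configured box, multi-starting from the
#' (alpha, H) grid with D initialised per start from a Gaussian-limit
#' log-linear regression. The lowest-SSE start wins; ties resolve to the
#' earlier start in grid order.
#'
#' @param attenuation numeric vector of S/S0, one per (Delta, G0) cell.
#' @param scheme an `fm_scheme`.
#' @param cells the cell table matching `attenuation` (defaults to
#'   `scheme_cells(scheme)`).
#' @param config an [fm_fit_config()].
#' @return list of class `fm_fit`: `params` ([fm_params()]), `mu`, `sse`,
#'   `converged`, `n_starts_used`, `unfittable`.
#' @export
fit_fm_voxel <- function(attenuation, scheme, cells = NULL,
                         config = fm_fit_config()) {
  stopifnot(inherits(scheme, "fm_scheme"))
  if (is.null(cells)) cells <- scheme_cells(scheme)
  ok <- is.finite(attenuation)
  unfit <- structure(list(params = NULL, mu = NA_real_, sse = NA_real_,
                          converged = FALSE, n_starts_used = 0L,
                          unfittable = TRUE), class = "fm_fit")
  if (sum(ok) < 3 || all(attenuation[ok] <= 0)) return(unfit)
  obs <- pmin(pmax(attenuation[ok], 1e-6), 1)  # physical attenuation range
  lu <- .fm_log_unit_exponent(scheme, Delta = cells$Delta[ok],
                              G0 = cells$G0[ok], eta_model = config$eta_model)
  a <- lu$a; b <- lu$b
  bl <- c(config$bounds$D[1], config$bounds$alpha[1], config$bounds$hurst[1])
  bu <- c(config$bounds$D[2], config$bounds$alpha[2], config$bounds$hurst[2])

  best <- NULL; best_sse <- Inf; n_starts <- 0L; best_conv <- FALSE
  for (h0 in config$init_hurst) for (a0 in config$init_alpha) {
    # D seed: Gaussian-limit log-linear fit at this start's (alpha, H)
    K <- exp(a0 * a + a0 * h0 * b)
    D0 <- max(sum(K * (-log(obs))) / sum(K * K), bl[1])
    p0 <- pmin(pmax(c(D0, a0, h0), bl), bu)
    n_starts <- n_starts + 1L
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = p0, lower = bl, upper = bu,
        fn = .fm_residual, jac = .fm_jacobian,
        a = a, b = b, obs = obs,
        control = minpack.lm::nls.lm.control(
          ftol = config$ftol, maxiter = min(config$maxiter, 1024))),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(fit$fvec^2)
    if (is.finite(sse) && sse < best_sse) {
      best_sse <- sse; best <- fit$par
      best_conv <- fit$info %in% 1:4
    }
  }
  if (is.null(best)) return(unfit)
  params <- fm_params(best[1], best[2], best[3])
  structure(list(params = params, mu = params$mu, sse = best_sse,
                 converged = best_conv, n_starts_used = n_starts,
                 unfittable = FALSE), class = "fm_fit")
}

#' Two-point apparent diffusion coefficient
#'
#' ADC = ln(S_b0 / S_b1) / b1 from one unweighted and one weighted signal.
#' Negative values (possible under noise) are returned as-is; callers count
#' them in QC.
#'
#' @param S_b0 signal at b = 0, > 0.
#' @param S_b1 signal at `b1`, > 0.
#' @param b1 the weighted b-value, s/mm^2, > 0.
#' @return adc in mm^2/s; `NA` where either signal is non-positive.
#' @export
compute_adc <- function(S_b0, S_b1, b1) {
  if (any(!is.finite(b1)) || any(b1 <= 0)) stop("b1 must be positive")
  out <- log(S_b0 / S_b1) / b1
  out[!is.finite(S_b0) | !is.finite(S_b1) | S_b0 <= 0 | S_b1 <= 0] <- NA_real_
  out
}

# index of the cell whose b is nearest target (ties -> lower b)
.adc_cell_index <- function(cells, target) {
  d <- abs(cells$bvalue - target)
  cand <- which(d == min(d))
  cand[which.min(cells$bvalue[cand])]
}

#' Fit FM parameters and ADC over a masked volume
#'
#' Runs [normalize_and_average()] then [fit_fm_voxel()] for every voxel in
#' the mask, and computes the two-point ADC from the direction-averaged
#' attenuation at the cell nearest `adc_b_target`. Deterministic given
#' inputs and configuration.
#'
#' @param dwi4d 4D array in scheme volume order.
#' @param mask 3D logical array (NULL = all voxels).
#' @param scheme an `fm_scheme`.
#' @param config an [fm_fit_config()].
#' @return list of class `fm_maps`: 3D arrays `alpha`, `hurst`, `mu`, `D`,
#'   `adc` (NA outside mask and at unfittable voxels), the `mask`, the
#'   `adc_bvalue` actually used, and `qc` (fitted / unfittable /
#'   non-converged counts, negative-ADC count).
#' @export
fit_fm_volume <- function(dwi4d, mask, scheme, config = fm_fit_config()) {
  stopifnot(inherits(scheme, "fm_scheme"))
  spat <- dim(dwi4d)[1:3]
  if (is.null(mask)) mask <- array(TRUE, spat)
  if (!identical(dim(mask), spat)) stop("mask shape does not match volume")
  mask <- array(as.logical(mask), spat)

  nm <- normalize_and_average(dwi4d, scheme, mask = mask, config = config)
  # unfittable/unmasked voxels carry NaN, which survives NIfTI round-trips
  maps <- list(alpha = array(NaN, spat), hurst = array(NaN, spat),
               mu = array(NaN, spat), D = array(NaN, spat),
               adc = array(NaN, spat))
  adc_ci <- .adc_cell_index(nm$cells, config$adc_b_target)
  adc_b <- nm$cells$bvalue[adc_ci]
  n_unfit <- 0L; n_nonconv <- 0L; n_fit <- 0L
  for (i in seq_along(nm$voxel_index)) {
    vi <- nm$voxel_index[i]
    if (nm$unfittable[i]) { n_unfit <- n_unfit + 1L; next }
    fit <- fit_fm_voxel(nm$attenuation[i, ], scheme, cells = nm$cells,
                        config = config)
    if (fit$unfittable) { n_unfit <- n_unfit + 1L; next }
    n_fit <- n_fit + 1L
    if (!fit$converged) n_nonconv <- n_nonconv + 1L
    maps$alpha[vi] <- fit$params$alpha
    maps$hurst[vi] <- fit$params$hurst
    maps$mu[vi] <- fit$mu
    maps$D[vi] <- fit$params$D
    maps$adc[vi] <- compute_adc(1, nm$attenuation[i, adc_ci], adc_b)
  }
  qc <- list(n_mask = sum(mask), n_fitted = n_fit, n_unfittable = n_unfit,
             n_nonconverged = n_nonconv,
             n_negative_adc = sum(maps$adc < 0, na.rm = TRUE),
             adc_bvalue = adc_b)
  structure(list(alpha = maps$alpha, hurst = maps$hurst, mu = maps$mu,
                 D = maps$D, adc = maps$adc, mask = mask,
                 adc_bvalue = adc_b, qc = qc),
            class = "fm_maps")
}

#' @export
print.fm_maps <- function(x, ...) {
  cat(sprintf("<fm_maps> %s voxels; fitted %d, unfittable %d (ADC b = %.0f)\n",
              paste(dim(x$mask), collapse = "x"),
              x$qc$n_fitted, x$qc$n_unfittable, x$adc_bvalue))
  invisible(x)
}
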