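# Digital cohort generation.
#
# No imaging data were deposited by clinical FM studies of the hippocampus,
# so every downstream stage is exercised on synthetic cohorts: per-subject
# "true" hippocampal FM parameters and ADC drawn from published group
# means/SDs, block phantoms imaged under the 18-b-value protocol, and
# Rician magnitude noise. The memory parameter mu is always derived as
# H - 1/alpha, never sampled.

#' Group specification for cohort simulation
#'
#' Describes one diagnostic group: sample size, per-hemisphere means and SDs
#' of alpha, H and ADC (mu is derived, not sampled), age and cognitive-score
#' distributions, and the target correlation between cognitive scores and
#' hippocampal alpha.
#'
#' @param name group label.
#' @param n number of subjects, >= 1.
#' @param alpha,hurst,adc named lists with `mean` and `sd` vectors of length
#'   2 (left, right). ADC in mm^2/s.
#' @param age,mmse,moca two-element vectors c(mean, sd); `moca = NULL` if the
#'   scale was not collected for this group.
#' @param p_male probability a subject is male.
#' @param score_alpha_r target correlation between each cognitive score and
#'   the subject's mean bilateral alpha.
#' @return a list of class `fm_group_spec`.
#' @export
group_spec <- function(name, n, alpha, hurst, adc, age,
                       mmse, moca = NULL, p_male = 0.5,
                       score_alpha_r = 0.45) {
  stopifnot(n >= 1, length(alpha$mean) == 2, length(hurst$mean) == 2,
            length(adc$mean) == 2)
  if (any(alpha$sd < 0, hurst$sd < 0, adc$sd < 0)) stop("SDs must be >= 0")
  .check_fm_params(alpha$mean, hurst$mean)
  if (any(adc$mean <= 0)) stop("adc means must be positive")
  if (abs(score_alpha_r) > 1) stop("score_alpha_r must lie in [-1, 1]")
  structure(list(name = name, n = as.integer(n), alpha = alpha,
                 hurst = hurst, adc = adc, age = age, mmse = mmse,
                 moca = moca, p_male = p_male,
                 score_alpha_r = score_alpha_r),
            class = "fm_group_spec")
}

#' Reference cohort specification
#'
#' The default three-group cohort emulating a hippocampal FM study of
#' Alzheimer's disease: 11 healthy controls, 12 mild AD and 12 moderate AD
#' subjects, with per-hemisphere alpha, H and ADC means/SDs, ages and
#' MMSE/MoCA score distributions taken from the published group summaries.
#' MoCA was not collected for controls and is generated as NA there.
#'
#' @param score_alpha_r target score-alpha correlation (cohort-wide default
#'   0.45; the published study reports a significant positive correlation
#'   without printing its magnitude).
#' @return named list of [group_spec()] objects
#'   (controls, mild_AD, moderate_AD).
#' @export
reference_cohort_spec <- function(score_alpha_r = 0.45) {
  list(
    controls = group_spec(
      "controls", 11,
      alpha = list(mean = c(1.588, 1.604), sd = c(0.047, 0.049)),
      hurst = list(mean = c(0.464, 0.479), sd = c(0.033, 0.028)),
      adc = list(mean = c(0.00108, 0.00104), sd = c(0.00013, 0.00012)),
      age = c(65.27, 6.60), mmse = c(28.82, 1.08), moca = NULL,
      p_male = 2 / 11, score_alpha_r = score_alpha_r),
    mild_AD = group_spec(
      "mild_AD", 12,
      alpha = list(mean = c(1.563, 1.562), sd = c(0.030, 0.040)),
      hurst = list(mean = c(0.470, 0.485), sd = c(0.027, 0.040)),
      adc = list(mean = c(0.00119, 0.00115), sd = c(0.00013, 0.00017)),
      age = c(65.83, 10.06), mmse = c(23.17, 11.27), moca = c(19.50, 2.39),
      p_male = 6 / 12, score_alpha_r = score_alpha_r),
    moderate_AD = group_spec(
      "moderate_AD", 12,
      alpha = list(mean = c(1.531, 1.519), sd = c(0.045, 0.041)),
      hurst = list(mean = c(0.468, 0.481), sd = c(0.030, 0.049)),
      adc = list(mean = c(0.00139, 0.00137), sd = c(0.00021, 0.00025)),
      age = c(72.08, 3.75), mmse = c(19.08, 1.44), moca = c(16.50, 2.15),
      p_male = 3 / 12, score_alpha_r = score_alpha_r)
  )
}

# truncated-normal draws by rejection; degenerate sd = 0 returns the mean
.rtrunc_norm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (mean < lower || mean > upper) stop("mean outside truncation bounds")
  if (sd == 0) return(rep(mean, n))
  out <- numeric(n); need <- seq_len(n)
  while (length(need)) {
    draw <- rnorm(length(need), mean, sd)
    ok <- draw >= lower & draw <= upper
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  out
}

# parameter legal ranges used for truncation (inside fitting bounds)
.trunc_bounds <- list(alpha = c(0.5, 2.0), hurst = c(0.05, 0.95),
                      adc = c(1e-6, Inf), age = c(0, Inf),
                      score = c(0, 30))

#' Sample per-subject true parameters and covariates for one group
#'
#' Draws each subject's left/right alpha, H and ADC from normal
#' distributions truncated to their legal ranges, ages and sexes from the
#' group spec, and cognitive scores as a linear function of the subject's
#' standardised mean bilateral alpha plus Gaussian noise, calibrated so the
#' population score-alpha correlation equals `spec$score_alpha_r`. mu is
#' computed from alpha and H, never sampled. Uses the current RNG state.
#'
#' @param spec a [group_spec()].
#' @return data.frame, one row per subject: group, age, sex, mmse, moca,
#'   alpha/hurst/mu/adc for left and right (columns suffixed `_left`,
#'   `_right`).
#' @export
sample_group_params <- function(spec) {
  stopifnot(inherits(spec, "fm_group_spec"))
  n <- spec$n
  tb <- .trunc_bounds
  al <- .rtrunc_norm(n, spec$alpha$mean[1], spec$alpha$sd[1], tb$alpha[1], tb$alpha[2])
  ar <- .rtrunc_norm(n, spec$alpha$mean[2], spec$alpha$sd[2], tb$alpha[1], tb$alpha[2])
  hl <- .rtrunc_norm(n, spec$hurst$mean[1], spec$hurst$sd[1], tb$hurst[1], tb$hurst[2])
  hr <- .rtrunc_norm(n, spec$hurst$mean[2], spec$hurst$sd[2], tb$hurst[1], tb$hurst[2])
  dl <- .rtrunc_norm(n, spec$adc$mean[1], spec$adc$sd[1], tb$adc[1], tb$adc[2])
  dr <- .rtrunc_norm(n, spec$adc$mean[2], spec$adc$sd[2], tb$adc[1], tb$adc[2])
  age <- .rtrunc_norm(n, spec$age[1], spec$age[2], tb$age[1], tb$age[2])
  sex <- ifelse(runif(n) < spec$p_male, "M", "F")

  # score = mean + sd*(r*z_alpha + sqrt(1-r^2)*eps): corr(score, alpha) -> r
  # z standardises the bilateral mean, whose SD is sqrt(sd_l^2 + sd_r^2)/2
  amu <- mean(c(spec$alpha$mean)); asd <- sqrt(sum(spec$alpha$sd^2)) / 2
  z <- if (asd > 0) ((al + ar) / 2 - amu) / asd else rep(0, n)
  r <- spec$score_alpha_r
  gen_score <- function(ms) {
    if (is.null(ms)) return(rep(NA_real_, n))
    raw <- ms[1] + ms[2] * (r * z + sqrt(1 - r^2) * rnorm(n))
    pmin(pmax(raw, tb$score[1]), tb$score[2])
  }
  mmse <- gen_score(spec$mmse)
  moca <- gen_score(spec$moca)

  data.frame(group = spec$name, age = age, sex = sex, mmse = mmse, moca = moca,
             alpha_left = al, alpha_right = ar,
             hurst_left = hl, hurst_right = hr,
             mu_left = memory_parameter(al, hl),
             mu_right = memory_parameter(ar, hr),
             adc_left = dl, adc_right = dr,
             stringsAsFactors = FALSE)
}

#' Rician magnitude noise
#'
#' Returns |signal + n1 + i n2| with n1, n2 independent N(0, sigma): the
#' magnitude-MRI noise model. Second moment is signal^2 + 2 sigma^2; at
#' signal = 0 the output is Rayleigh with mean sigma*sqrt(pi/2).
#'
#' @param signal non-negative signal amplitude(s).
#' @param sigma per-channel noise SD, >= 0. Typically `S0 / SNR`.
#' @return noisy magnitude(s), same length as `signal`.
#' @export
add_rician_noise <- function(signal, sigma) {
  if (any(!is.finite(signal)) || any(signal < 0)) stop("signal must be >= 0")
  if (!is.finite(sigma) || sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(signal)
  n <- length(signal)
  sqrt((signal + rnorm(n, 0, sigma))^2 + rnorm(n, 0, sigma)^2)
}

# cell used to calibrate D from ADC: median b among distinct cells
# (lower median for an even count)
.mid_cell_index <- function(cells) {
  ord <- order(cells$bvalue)
  ord[ceiling(length(ord) / 2)]
}

#' Anomalous D consistent with a target ADC
#'
#' Chooses the FM diffusion coefficient so that the FM attenuation at the
#' scheme's median-b cell equals the mono-exponential attenuation
#' exp(-b * adc) at that cell, keeping phantom signal levels realistic for
#' a given subject ADC.
#'
#' @param alpha,hurst FM exponents.
#' @param adc target apparent diffusion coefficient, mm^2/s.
#' @param scheme an `fm_scheme`.
#' @return D in model units (mm^alpha s^(-alpha*H)).
#' @export
calibrate_D_from_adc <- function(alpha, hurst, adc, scheme) {
  cells <- scheme_cells(scheme)
  ci <- .mid_cell_index(cells)
  lu <- .fm_log_unit_exponent(scheme, Delta = cells$Delta[ci], G0 = cells$G0[ci])
  cells$bvalue[ci] * adc / exp(alpha * lu$a + alpha * hurst * lu$b)
}

#' Default phantom geometry
#'
#' A 16 x 16 x 4 volume with two disjoint 3 x 3 x 2 block ROIs standing in
#' for the left and right hippocampus.
#'
#' @param shape spatial dimensions.
#' @return list with `shape` and logical arrays `roi_left`, `roi_right`.
#' @export
phantom_geometry <- function(shape = c(16, 16, 4)) {
  if (any(shape < c(10, 8, 2))) stop("shape too small for two disjoint ROIs")
  zr <- if (shape[3] >= 3) 2:3 else 1:2
  left <- array(FALSE, shape); right <- array(FALSE, shape)
  left[3:5, 3:5, zr] <- TRUE
  right[(shape[1] - 4):(shape[1] - 2), 3:5, zr] <- TRUE
  if (any(left & right)) stop("ROIs overlap")
  list(shape = shape, roi_left = left, roi_right = right)
}

#' Generate one subject's phantom volume
#'
#' Builds a 4D series in scheme volume order: inside each ROI, noiseless FM
#' signals from that hemisphere's true parameters at amplitude `S0`;
#' background voxels at a low constant amplitude; Rician noise with
#' sigma = S0/snr applied to every voxel of every volume (snr = Inf for a
#' noiseless phantom). Uses the current RNG state.
#'
#' @param subject one row of [sample_group_params()] output (needs
#'   alpha/hurst/adc `_left`/`_right` columns).
#' @param scheme an `fm_scheme`.
#' @param geometry a [phantom_geometry()].
#' @param snr signal-to-noise ratio at S0.
#' @param S0 ROI unweighted amplitude.
#' @param background_frac background amplitude as a fraction of S0.
#' @return list with `dwi` (4D array), `roi_left`, `roi_right`, `truth`
#'   (per-hemisphere [fm_params()] plus adc).
#' @export
generate_phantom <- function(subject, scheme, geometry = phantom_geometry(),
                             snr = 50, S0 = 1000, background_frac = 0.1) {
  stopifnot(inherits(scheme, "fm_scheme"))
  if (any(geometry$roi_left & geometry$roi_right)) stop("ROIs overlap")
  nvol <- scheme_n_volumes(scheme)
  shape <- geometry$shape
  truth <- list(
    left = fm_params(
      calibrate_D_from_adc(subject$alpha_left, subject$hurst_left,
                           subject$adc_left, scheme),
      subject$alpha_left, subject$hurst_left),
    right = fm_params(
      calibrate_D_from_adc(subject$alpha_right, subject$hurst_right,
                           subject$adc_right, scheme),
      subject$alpha_right, subject$hurst_right),
    adc_left = subject$adc_left, adc_right = subject$adc_right)

  dwi <- array(S0 * background_frac, c(shape, nvol))
  fill_roi <- function(dwi, roi, params) {
    sig <- c(rep(S0, scheme$n_b0), fm_signal(params, scheme, S0 = S0))
    vox <- which(roi)
    for (v in seq_len(nvol)) {
      vol <- dwi[, , , v]
      vol[vox] <- sig[v]
      dwi[, , , v] <- vol
    }
    dwi
  }
  dwi <- fill_roi(dwi, geometry$roi_left, truth$left)
  dwi <- fill_roi(dwi, geometry$roi_right, truth$right)
  if (is.finite(snr)) {
    if (snr <= 0) stop("snr must be positive")
    dwi <- array(add_rician_noise(as.vector(dwi), S0 / snr), dim(dwi))
  }
  list(dwi = dwi, roi_left = geometry$roi_left,
       roi_right = geometry$roi_right, truth = truth)
}

# deterministic per-subject seed stream below 2^31, from master seed + index
.subject_seed <- function(seed, idx) {
  as.integer((as.numeric(seed) * 48271 + idx * 16807) %% 2147483647)
}

#' Generate a full synthetic cohort
#'
#' Samples every group's subjects ([sample_group_params()]), then (optionally)
#' renders each subject's phantom under the scheme at the requested SNR.
#' Fully reproducible from `seed`: covariates use one stream seeded by
#' `seed`, and each subject's phantom uses a stream derived from
#' (seed, subject index). If `dir` is given, writes NIfTI phantoms and
#' masks, the scheme JSON, and `subjects.csv` there.
#'
#' @param specs named list of [group_spec()]s
#'   (default [reference_cohort_spec()]).
#' @param scheme an `fm_scheme` (default [default_scheme()]).
#' @param snr phantom SNR at S0 (Inf = noiseless).
#' @param seed integer master seed (mandatory).
#' @param phantoms if FALSE, skip volume rendering (covariates/truth only).
#' @param geometry a [phantom_geometry()].
#' @param dir optional output directory.
#' @return list of class `fm_cohort`: `subjects` (data.frame with id, group,
#'   covariates and true parameters), `phantoms` (list or NULL), `scheme`,
#'   `seed`.
#' @export
generate_cohort <- function(specs = reference_cohort_spec(),
                            scheme = default_scheme(), snr = 50, seed,
                            phantoms = TRUE, geometry = phantom_geometry(),
                            dir = NULL) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  nm <- vapply(specs, function(s) s$name, character(1))
  if (anyDuplicated(nm)) stop("duplicate group names")
  set.seed(as.integer(seed) %% 2147483647)
  subjects <- do.call(rbind, lapply(specs, sample_group_params))
  subjects <- cbind(id = sprintf("sub-%03d", seq_len(nrow(subjects))),
                    subjects, stringsAsFactors = FALSE)
  rownames(subjects) <- NULL

  ph <- NULL
  if (phantoms) {
    ph <- vector("list", nrow(subjects))
    names(ph) <- subjects$id
    for (i in seq_len(nrow(subjects))) {
      set.seed(.subject_seed(seed, i))
      ph[[i]] <- generate_phantom(subjects[i, ], scheme,
                                  geometry = geometry, snr = snr)
    }
  }
  cohort <- structure(list(subjects = subjects, phantoms = ph,
                           scheme = scheme, seed = seed, snr = snr),
                      class = "fm_cohort")
  if (!is.null(dir)) write_cohort(cohort, dir)
  cohort
}

#' @export
print.fm_cohort <- function(x, ...) {
  cat(sprintf("<fm_cohort> %d subjects (%s), seed %s, %s phantoms\n",
              nrow(x$subjects),
              paste(sprintf("%s: %d", names(table(x$subjects$group)),
                            table(x$subjects$group)), collapse = ", "),
              format(x$seed),
              if (is.null(x$phantoms)) "no" else "with"))
  invisible(x)
}
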