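# Cohort-level orchestration: fit every subject's phantom (or supplied
# volumes), reduce maps to ROI means, and run the full statistics battery.

.param_cols <- c("alpha", "hurst", "mu", "adc")
.roi_sides <- c("left", "right")

#' ROI-mean subject records from fitted maps
#'
#' Reduces one subject's parameter maps to per-hemisphere ROI means.
#'
#' @param maps an `fm_maps` object.
#' @param roi_left,roi_right 3D logical ROI masks.
#' @return named list `alpha_left`, ..., `adc_right` of ROI means.
#' @export
roi_summary <- function(maps, roi_left, roi_right) {
  stopifnot(inherits(maps, "fm_maps"))
  out <- list()
  for (p in .param_cols) {
    out[[paste0(p, "_left")]] <- roi_mean(maps[[p]], roi_left)$mean
    out[[paste0(p, "_right")]] <- roi_mean(maps[[p]], roi_right)$mean
  }
  out
}

#' Fit a cohort's phantoms and build the subject table
#'
#' Runs [fit_fm_volume()] on each subject's phantom restricted to the union
#' of the ROI masks (optionally one hemisphere) and assembles the analysis
#' table of fitted ROI means alongside covariates.
#'
#' @param cohort an `fm_cohort` with phantoms.
#' @param config an [fm_fit_config()].
#' @param sides which hemispheres to fit, subset of c("left", "right").
#' @return data.frame: id, group, age, sex, mmse, moca, and fitted
#'   `<param>_<side>` columns for the requested sides.
#' @export
fit_cohort <- function(cohort, config = fm_fit_config(),
                       sides = c("left", "right")) {
  stopifnot(inherits(cohort, "fm_cohort"))
  if (is.null(cohort$phantoms)) stop("cohort has no phantoms")
  sides <- match.arg(sides, several.ok = TRUE)
  rows <- vector("list", nrow(cohort$subjects))
  for (i in seq_len(nrow(cohort$subjects))) {
    ph <- cohort$phantoms[[i]]
    mask <- Reduce(`|`, lapply(sides, function(s) ph[[paste0("roi_", s)]]))
    maps <- fit_fm_volume(ph$dwi, mask, cohort$scheme, config = config)
    rec <- list()
    for (s in sides) for (p in .param_cols)
      rec[[paste0(p, "_", s)]] <- roi_mean(maps[[p]], ph[[paste0("roi_", s)]])$mean
    rows[[i]] <- as.data.frame(rec)
  }
  cbind(cohort$subjects[, c("id", "group", "age", "sex", "mmse", "moca")],
        do.call(rbind, rows))
}

.require_cols <- function(df, cols) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop("missing required columns: ", paste(missing, collapse = ", "))
}

#' Run the full group-discrimination analysis
#'
#' Reproduces the statistics battery of a hippocampal FM group study on a
#' subject table: per-parameter, per-hemisphere two-sample t-tests for
#' patients vs controls and mild vs moderate; ROC/AUC with Youden
#' thresholds for alpha, ADC, the logistic combination alpha + ADC and the
#' four-marker combination alpha + ADC + H + mu; and Pearson partial
#' correlations (adjusting for age) of each parameter with each cognitive
#' scale within patients, with Benjamini-Hochberg FDR over that correlation
#' family. Output is deterministic and invariant to subject order.
#'
#' @param subjects data.frame with columns id, group, age, mmse, moca and
#'   `<param>_<side>` for alpha, hurst, mu, adc and left, right.
#' @param groups named list mapping role to group label(s):
#'   `control`, `mild`, `moderate`.
#' @param ttest_variant `"pooled"` or `"welch"`.
#' @param covariates covariate column names for the partial correlations.
#' @return list of class `fm_report`: `ttests`, `roc`, `correlations`
#'   (data.frames) and `config`.
#' @export
run_group_analysis <- function(subjects,
                               groups = list(control = "controls",
                                             mild = "mild_AD",
                                             moderate = "moderate_AD"),
                               ttest_variant = c("pooled", "welch"),
                               covariates = "age") {
  ttest_variant <- match.arg(ttest_variant)
  roi_cols <- as.vector(outer(.param_cols, .roi_sides, paste, sep = "_"))
  .require_cols(subjects, c("id", "group", "age", "mmse", "moca", roi_cols))
  subjects <- subjects[order(subjects$id), , drop = FALSE]  # order invariance

  is_ad <- subjects$group %in% c(groups$mild, groups$moderate)
  is_ctrl <- subjects$group %in% groups$control
  is_mild <- subjects$group %in% groups$mild
  is_mod <- subjects$group %in% groups$moderate

  contrasts <- list(
    AD_vs_control = list(a = is_ad, b = is_ctrl),
    moderate_vs_mild = list(a = is_mod, b = is_mild))

  tt <- do.call(rbind, lapply(names(contrasts), function(cn) {
    ct <- contrasts[[cn]]
    do.call(rbind, lapply(roi_cols, function(col) {
      r <- two_sample_ttest(subjects[[col]][ct$a], subjects[[col]][ct$b],
                            variant = ttest_variant)
      data.frame(contrast = cn, measure = col, statistic = r$statistic,
                 df = r$df, p = r$p, stringsAsFactors = FALSE)
    }))
  }))

  marker_sets <- list(alpha = "alpha", adc = "adc",
                      `alpha+adc` = c("alpha", "adc"),
                      `alpha+adc+hurst+mu` = c("alpha", "adc", "hurst", "mu"))
  roc <- do.call(rbind, lapply(names(contrasts), function(cn) {
    ct <- contrasts[[cn]]
    sel <- ct$a | ct$b
    labels <- ct$a[sel]
    do.call(rbind, lapply(.roi_sides, function(side) {
      do.call(rbind, lapply(names(marker_sets), function(ms) {
        cols <- paste0(marker_sets[[ms]], "_", side)
        X <- subjects[sel, cols, drop = FALSE]
        if (length(cols) == 1) {
          r <- roc_analysis(X[[1]], labels)
          data.frame(contrast = cn, roi = side, markers = ms, auc = r$auc,
                     threshold = r$threshold, sensitivity = r$sensitivity,
                     specificity = r$specificity, youden = r$youden,
                     direction = r$direction, stringsAsFactors = FALSE)
        } else {
          cm <- suppressWarnings(combine_markers(X, labels))
          r <- roc_analysis(cm$score, labels)
          data.frame(contrast = cn, roi = side, markers = ms, auc = r$auc,
                     threshold = NA_real_, sensitivity = r$sensitivity,
                     specificity = r$specificity, youden = r$youden,
                     direction = r$direction, stringsAsFactors = FALSE)
        }
      }))
    }))
  }))

  ad <- subjects[is_ad, , drop = FALSE]
  Z <- as.matrix(ad[, covariates, drop = FALSE])
  cors <- do.call(rbind, lapply(c("mmse", "moca"), function(scale) {
    do.call(rbind, lapply(roi_cols, function(col) {
      pc <- partial_correlation(ad[[col]], ad[[scale]], Z)
      data.frame(scale = scale, measure = col, r = pc$r, p = pc$p,
                 df = pc$df, n = pc$n, stringsAsFactors = FALSE)
    }))
  }))
  cors$q <- bh_fdr(cors$p)

  structure(list(ttests = tt, roc = roc, correlations = cors,
                 config = list(ttest_variant = ttest_variant,
                               covariates = covariates, groups = groups)),
            class = "fm_report")
}

#' @export
print.fm_report <- function(x, ...) {
  cat("<fm_report>\n t-tests:\n")
  print(x$ttests, digits = 4)
  cat(" ROC:\n")
  print(x$roc, digits = 4)
  cat(" partial correlations (FDR-adjusted q):\n")
  print(x$correlations, digits = 4)
  invisible(x)
}
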