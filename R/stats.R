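# ROI summarisation and the group-discrimination statistics battery:
# two-sample t-tests (raw data or sufficient statistics), ROC/AUC with
# Youden-index thresholds, logistic marker combination, Pearson partial
# correlation, and Benjamini-Hochberg FDR control.

#' Mean of a map over a mask
#'
#' Arithmetic mean of the finite voxels of `map` inside `mask`; non-finite
#' voxels are excluded and counted.
#'
#' @param map 3D numeric array.
#' @param mask 3D logical array of the same shape, with at least one voxel.
#' @return list with `mean` (NA if no finite voxel), `n_used`,
#'   `n_excluded`.
#' @export
roi_mean <- function(map, mask) {
  if (!identical(dim(map), dim(mask))) stop("map and mask shapes differ")
  mask <- as.logical(mask)
  if (!any(mask)) stop("mask is empty")
  vals <- map[which(mask)]
  ok <- is.finite(vals)
  list(mean = if (any(ok)) mean(vals[ok]) else NA_real_,
       n_used = sum(ok), n_excluded = sum(!ok))
}

.t_from_summary <- function(m1, sd1, n1, m2, sd2, n2,
                            variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  if (n1 < 2 || n2 < 2) stop("each group needs n >= 2")
  if (sd1 < 0 || sd2 < 0) stop("SDs must be >= 0")
  if (sd1 == 0 && sd2 == 0) {
    if (m1 == m2) return(list(statistic = 0, df = n1 + n2 - 2, p = 1))
    return(list(statistic = sign(m1 - m2) * Inf, df = n1 + n2 - 2, p = 0))
  }
  if (variant == "pooled") {
    df <- n1 + n2 - 2
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  } else {
    v1 <- sd1^2 / n1; v2 <- sd2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  t <- (m1 - m2) / se
  list(statistic = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Two-sample t-test
#'
#' Pooled-variance Student's test by default; Welch by `variant = "welch"`.
#' Two-sided p-values.
#'
#' @param x,y numeric vectors, each of length >= 2.
#' @param variant `"pooled"` or `"welch"`.
#' @return list of class `fm_test`: `statistic`, `df`, `p`, `variant`.
#' @export
two_sample_ttest <- function(x, y, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 2 || length(y) < 2) stop("each group needs n >= 2 finite values")
  res <- .t_from_summary(mean(x), stats::sd(x), length(x),
                         mean(y), stats::sd(y), length(y), variant)
  structure(c(res, list(variant = variant)), class = "fm_test")
}

#' Two-sample t-test from sufficient statistics
#'
#' Identical formulas to [two_sample_ttest()] but from means, sample SDs
#' (n - 1 denominator) and counts — the form needed to test published
#' group summaries against each other.
#'
#' @param m1,sd1,n1 first group's mean, SD, size.
#' @param m2,sd2,n2 second group's mean, SD, size.
#' @param variant `"pooled"` or `"welch"`.
#' @return list of class `fm_test`.
#' @export
ttest_from_summary <- function(m1, sd1, n1, m2, sd2, n2,
                               variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  structure(c(.t_from_summary(m1, sd1, n1, m2, sd2, n2, variant),
              list(variant = variant)), class = "fm_test")
}

#' @export
print.fm_test <- function(x, ...) {
  cat(sprintf("<fm_test %s> t = %.4f, df = %.2f, p = %.4g\n",
              x$variant, x$statistic, x$df, x$p))
  invisible(x)
}

#' Pool two subgroups' summaries exactly
#'
#' Combines (mean, SD, n) of two disjoint subgroups into the exact mean, SD
#' and n of their union (sample SD convention, n - 1 denominator) — e.g. to
#' form a combined patient group from published mild/moderate rows.
#'
#' @param m1,sd1,n1,m2,sd2,n2 subgroup summaries.
#' @return list with `mean`, `sd`, `n`.
#' @export
pool_summaries <- function(m1, sd1, n1, m2, sd2, n2) {
  if (n1 < 1 || n2 < 1) stop("n must be >= 1")
  n <- n1 + n2
  m <- (n1 * m1 + n2 * m2) / n
  ss <- (n1 - 1) * sd1^2 + (n2 - 1) * sd2^2 +
    n1 * (m1 - m)^2 + n2 * (m2 - m)^2
  list(mean = m, sd = sqrt(ss / (n - 1)), n = n)
}

#' Empirical ROC curve, AUC and Youden threshold
#'
#' Builds the empirical ROC over all distinct score thresholds, computes the
#' trapezoidal AUC (equal to the Mann-Whitney concordance with ties counted
#' 1/2), and selects the Youden-optimal operating threshold. Orientation is
#' chosen automatically so AUC >= 0.5 and reported in `direction`:
#' `"high"` means larger scores indicate the positive class.
#'
#' Candidate thresholds are midpoints between adjacent distinct scores plus
#' -Inf and +Inf; a subject is called positive when its oriented score is
#' >= the oriented threshold. Ties in the Youden index resolve to the
#' smallest threshold (in oriented-score order).
#'
#' @param scores numeric marker values, one per subject.
#' @param labels positive-class indicator (logical, or 0/1, or a factor
#'   whose second level is positive).
#' @return list of class `fm_roc`: `curve` (data.frame fpr, tpr from (0,0)
#'   to (1,1)), `auc`, `direction`, `threshold` (marker units),
#'   `sensitivity`, `specificity`, `youden`.
#' @export
roc_analysis <- function(scores, labels) {
  if (is.factor(labels)) labels <- labels == levels(labels)[2]
  labels <- as.logical(labels)
  if (any(!is.finite(scores)) || any(is.na(labels)))
    stop("scores must be finite and labels non-missing")
  if (!any(labels) || all(labels)) stop("both classes must be present")

  auc_for <- function(s) {
    # Mann-Whitney with 0.5 per tie
    r <- rank(s)
    np <- sum(labels); nn <- sum(!labels)
    (sum(r[labels]) - np * (np + 1) / 2) / (np * nn)
  }
  direction <- if (auc_for(scores) >= 0.5) "high" else "low"
  s <- if (direction == "high") scores else -scores

  thr_or <- c(-Inf, sort(unique(s)))  # oriented thresholds: cutpoints below
  np <- sum(labels); nn <- sum(!labels)
  # classify positive when oriented score >= t; candidate t at midpoints
  su <- sort(unique(s))
  cand <- c(-Inf, if (length(su) > 1) (su[-1] + su[-length(su)]) / 2, Inf)
  sens <- vapply(cand, function(t) sum(s[labels] >= t) / np, numeric(1))
  spec <- vapply(cand, function(t) sum(s[!labels] < t) / nn, numeric(1))
  J <- sens + spec - 1
  best <- which(J == max(J))[1]  # cand is ascending: first max = smallest t

  # curve: thresholds descending -> (0,0) ... (1,1); tied scores one step
  tpr <- c(0, vapply(rev(su), function(t) sum(s[labels] >= t) / np, numeric(1)))
  fpr <- c(0, vapply(rev(su), function(t) sum(s[!labels] >= t) / nn, numeric(1)))
  curve <- data.frame(fpr = c(fpr, 1), tpr = c(tpr, 1))
  curve <- curve[!duplicated(curve), ]
  rownames(curve) <- NULL

  structure(list(
    curve = curve,
    auc = auc_for(s),
    direction = direction,
    threshold = if (direction == "high") cand[best] else -cand[best],
    sensitivity = sens[best], specificity = spec[best],
    youden = J[best]), class = "fm_roc")
}

#' @export
print.fm_roc <- function(x, ...) {
  cat(sprintf(
    "<fm_roc> AUC = %.3f (%s scores positive); Youden J = %.3f at %.4g (sens %.3f, spec %.3f)\n",
    x$auc, x$direction, x$youden, x$threshold, x$sensitivity, x$specificity))
  invisible(x)
}

#' Youden-optimal threshold
#'
#' Convenience wrapper around [roc_analysis()] returning the operating
#' point that maximises J = sensitivity + specificity - 1.
#'
#' @inheritParams roc_analysis
#' @return list with `threshold`, `sensitivity`, `specificity`, `youden`,
#'   `direction`.
#' @export
youden_threshold <- function(scores, labels) {
  r <- roc_analysis(scores, labels)
  r[c("threshold", "sensitivity", "specificity", "youden", "direction")]
}

# ridge-stabilised logistic IRLS (penalty on slopes, not the intercept)
.ridge_logistic <- function(X, y, lambda = 1e-6, maxit = 100, tol = 1e-8) {
  Xd <- cbind(1, X)
  p <- ncol(Xd)
  pen <- diag(c(0, rep(lambda, p - 1)), p)
  beta <- rep(0, p)
  for (it in seq_len(maxit)) {
    eta <- drop(Xd %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    H <- crossprod(Xd, Xd * w) + pen
    beta_new <- drop(solve(H, crossprod(Xd, w * z)))
    if (max(abs(beta_new - beta)) < tol) { beta <- beta_new; break }
    beta <- beta_new
  }
  beta
}

#' Combine markers into one diagnostic score
#'
#' Linear predictor of an unregularised maximum-likelihood logistic
#' regression of class on the marker matrix (intercept included, iteration
#' cap 100, tolerance 1e-8). Under perfect separation the ML optimum
#' diverges, so the score falls back to the direction of a
#' ridge-stabilised fit (penalty 1e-6) with a warning. Downstream ROC on
#' the returned score is invariant to monotone rescaling, so a single
#' feature's combined-score AUC equals that feature's own AUC.
#'
#' @param features numeric matrix or data.frame, one row per subject.
#' @param labels positive-class indicator as in [roc_analysis()].
#' @return list of class `fm_combined`: `score` (per subject),
#'   `coefficients`, `separated` (logical).
#' @export
combine_markers <- function(features, labels) {
  X <- as.matrix(features)
  storage.mode(X) <- "double"
  if (is.factor(labels)) labels <- labels == levels(labels)[2]
  y <- as.numeric(as.logical(labels))
  if (nrow(X) != length(y)) stop("features and labels lengths differ")
  if (any(!is.finite(X))) stop("features must be finite (no missing values)")
  if (min(table(y)) < 2) stop("need >= 2 subjects per class")

  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm.fit(cbind(1, X), y, family = stats::binomial(),
                   control = list(maxit = 100, epsilon = 1e-8)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (!fit$converged) sep <- TRUE
  beta <- fit$coefficients
  if (sep || anyNA(beta)) {
    warning("perfect separation: using ridge-stabilised direction")
    beta <- .ridge_logistic(X, y)
    sep <- TRUE
  }
  structure(list(score = drop(cbind(1, X) %*% beta),
                 coefficients = beta, separated = sep),
            class = "fm_combined")
}

#' Pearson partial correlation
#'
#' Correlation of x and y after removing the least-squares effect of the
#' covariates (with intercept) from each; with no covariates this is the
#' plain Pearson correlation. p-value from t = r sqrt((n-2-k)/(1-r^2)) on
#' n - 2 - k degrees of freedom.
#'
#' @param x,y numeric vectors.
#' @param covariates numeric vector, matrix or data.frame (NULL for none).
#' @return list of class `fm_pcor`: `r`, `p`, `df`, `n`, `n_covariates`.
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  ok <- is.finite(x) & is.finite(y)
  if (!is.null(covariates)) {
    Z <- as.matrix(covariates)
    ok <- ok & apply(is.finite(Z), 1, all)
  }
  x <- x[ok]; y <- y[ok]
  k <- 0L
  if (!is.null(covariates)) {
    Z <- as.matrix(covariates)[ok, , drop = FALSE]
    k <- ncol(Z)
    x <- stats::lm.fit(cbind(1, Z), x)$residuals
    y <- stats::lm.fit(cbind(1, Z), y)$residuals
  }
  n <- length(x)
  if (n <= 2 + k) stop("need n > 2 + number of covariates")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(structure(list(r = NA_real_, p = NA_real_, df = n - 2 - k,
                          n = n, n_covariates = k), class = "fm_pcor"))
  r <- stats::cor(x, y)
  df <- n - 2 - k
  t <- r * sqrt(df / (1 - r^2))
  structure(list(r = r, p = 2 * stats::pt(-abs(t), df), df = df, n = n,
                 n_covariates = k), class = "fm_pcor")
}

#' @export
print.fm_pcor <- function(x, ...) {
  cat(sprintf("<fm_pcor> r = %.4f, p = %.4g (df = %d, %d covariate%s)\n",
              x$r, x$p, x$df, x$n_covariates,
              if (x$n_covariates == 1) "" else "s"))
  invisible(x)
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up FDR-adjusted p-values, q(i) = min over j >= i of m p(j) / j after
#' ascending sort, mapped back to input order and capped at 1.
#'
#' @param pvalues numeric vector in \[0, 1\].
#' @return q-values in input order.
#' @export
bh_fdr <- function(pvalues) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0) || any(pvalues > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}
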