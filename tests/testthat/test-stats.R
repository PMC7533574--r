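test_that("roi_mean averages finite masked voxels and reports exclusions", {
  m <- array(2.5, c(3, 3, 1))
  mask <- array(TRUE, c(3, 3, 1))
  expect_equal(roi_mean(m, mask)$mean, 2.5)
  m2 <- array(NA_real_, c(2, 2, 1)); m2[1, 1, 1] <- 1; m2[2, 1, 1] <- 2
  mask2 <- array(FALSE, c(2, 2, 1)); mask2[, 1, 1] <- TRUE; mask2[1, 2, 1] <- TRUE
  r <- roi_mean(m2, mask2)
  expect_equal(r$mean, 1.5)
  expect_equal(r$n_excluded, 1)
  allna <- roi_mean(array(NA_real_, c(1, 1, 1)), array(TRUE, c(1, 1, 1)))
  expect_true(is.na(allna$mean))
  expect_error(roi_mean(m, array(FALSE, c(3, 3, 1))), "empty")
  expect_error(roi_mean(m, mask2), "shapes")
})

test_that("two-sample t-test matches the hand-computed pooled example", {
  r <- two_sample_ttest(c(1, 2, 3), c(2, 3, 4))
  expect_equal(r$statistic, -1.2247, tolerance = 1e-4)
  expect_equal(r$df, 4)
  same <- two_sample_ttest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  expect_error(two_sample_ttest(1, c(1, 2)), "n >= 2")
})

test_that("t-tests agree with stats::t.test and with their summary twin", {
  set.seed(14)
  for (i in 1:25) {
    x <- rnorm(sample(3:12, 1)); y <- rnorm(sample(3:12, 1), mean = 0.5)
    for (variant in c("pooled", "welch")) {
      mine <- two_sample_ttest(x, y, variant)
      ref <- t.test(x, y, var.equal = variant == "pooled")
      expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-12)
      expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
      froms <- ttest_from_summary(mean(x), sd(x), length(x),
                                  mean(y), sd(y), length(y), variant)
      expect_equal(froms$statistic / mine$statistic, 1, tolerance = 1e-10)
      expect_equal(froms$p / mine$p, 1, tolerance = 1e-10)
    }
  }
})

test_that("summary pooling reproduces exact full-sample mean and SD", {
  pooled <- pool_summaries(1.563, 0.030, 12, 1.531, 0.045, 12)
  expect_equal(pooled$mean, 1.547)
  expect_equal(pooled$n, 24)
  set.seed(3)
  x <- rnorm(9); y <- rnorm(14, 2)
  p2 <- pool_summaries(mean(x), sd(x), 9, mean(y), sd(y), 14)
  expect_equal(p2$mean, mean(c(x, y)), tolerance = 1e-12)
  expect_equal(p2$sd, sd(c(x, y)), tolerance = 1e-12)
  s <- ttest_from_summary(2, 1, 5, 2, 1, 8)
  expect_equal(s$statistic, 0)
})

test_that("ROC handles separation, ties and the pair-counting identity", {
  perfect <- roc_analysis(c(1, 2, 3, 4), c(0, 0, 1, 1))
  expect_equal(perfect$auc, 1)
  expect_equal(perfect$youden, 1)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)
  tied <- roc_analysis(rep(2, 6), c(0, 0, 0, 1, 1, 1))
  expect_equal(tied$auc, 0.5)
  ex <- roc_analysis(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
  expect_equal(ex$auc, 0.75)
  expect_error(roc_analysis(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("AUC equals Mann-Whitney concordance on random instances", {
  set.seed(21)
  brute_auc <- function(s, l) {
    pos <- s[l == 1]; neg <- s[l == 0]
    pairs <- outer(pos, neg, function(p, n) (p > n) + 0.5 * (p == n))
    mean(pairs)
  }
  for (i in 1:100) {
    n <- sample(6:20, 1)
    s <- sample(1:8, n, replace = TRUE) + round(rnorm(n), 1)
    l <- rbinom(n, 1, 0.5)
    if (length(unique(l)) < 2) next
    r <- roc_analysis(s, l)
    oriented <- if (r$direction == "high") s else -s
    expect_equal(r$auc, max(brute_auc(s, l), 1 - brute_auc(s, l)),
                 tolerance = 1e-12)
    # curve is monotone from (0,0) to (1,1)
    expect_equal(r$curve$fpr[1], 0); expect_equal(r$curve$tpr[1], 0)
    expect_equal(r$curve$fpr[nrow(r$curve)], 1)
    expect_true(all(diff(r$curve$fpr) >= 0) && all(diff(r$curve$tpr) >= 0))
    expect_equal(r$youden, r$sensitivity + r$specificity - 1)
  }
})

test_that("Youden threshold equals exhaustive search, ties resolve low", {
  tie <- youden_threshold(c(1, 2, 3, 4), c(0, 1, 0, 1))
  expect_equal(tie$youden, 0.5)
  expect_equal(tie$threshold, 1.5)  # smallest maximising cut-point

  set.seed(22)
  for (i in 1:100) {
    n <- sample(6:16, 1)
    s <- round(runif(n, 0, 4), 1)
    l <- rbinom(n, 1, 0.5)
    if (length(unique(l)) < 2) next
    r <- roc_analysis(s, l)
    or_s <- if (r$direction == "high") s else -s
    cand <- c(-Inf, sort(unique(or_s)) - 1e-9, sort(unique(or_s)) + 1e-9, Inf)
    J <- vapply(cand, function(t)
      mean(or_s[l == 1] >= t) + mean(or_s[l == 0] < t) - 1, numeric(1))
    expect_equal(r$youden, max(J), tolerance = 1e-9)
  }
})

test_that("marker combination preserves single-feature AUC and separates", {
  set.seed(30)
  x <- rnorm(20); l <- rbinom(20, 1, 0.5)
  if (length(unique(l)) < 2) l[1:2] <- c(0, 1)
  cm <- combine_markers(matrix(x, ncol = 1), l)
  expect_equal(roc_analysis(cm$score, l)$auc, roc_analysis(x, l)$auc)

  sepX <- cbind(c(rnorm(5), rnorm(5) + 20), rnorm(10))
  sepl <- rep(c(0, 1), each = 5)
  expect_warning(cmsep <- combine_markers(sepX, sepl), "separation")
  expect_true(cmsep$separated)
  expect_equal(roc_analysis(cmsep$score, sepl)$auc, 1)
  expect_error(combine_markers(matrix(NA_real_, 4, 1), c(0, 0, 1, 1)), "finite")
})

test_that("two-marker combination approaches the Gaussian closed-form AUC", {
  # bivariate normal groups, common covariance: optimal AUC is
  # pnorm(sqrt(delta' Sigma^-1 delta) / sqrt(2)); logistic combination is
  # asymptotically optimal, so at n = 5000 the empirical AUC should be close
  set.seed(31)
  n <- 5000
  Sigma <- matrix(c(1, 0.3, 0.3, 1), 2)
  Lc <- chol(Sigma)
  delta <- c(0.8, 0.5)
  X0 <- matrix(rnorm(2 * n), ncol = 2) %*% Lc
  X1 <- sweep(matrix(rnorm(2 * n), ncol = 2) %*% Lc, 2, delta, `+`)
  X <- rbind(X0, X1); l <- rep(c(0, 1), each = n)
  cm <- combine_markers(X, l)
  auc <- roc_analysis(cm$score, l)$auc
  auc_closed <- pnorm(sqrt(drop(t(delta) %*% solve(Sigma) %*% delta)) / sqrt(2))
  expect_equal(auc, auc_closed, tolerance = 0.015)
})

test_that("partial correlation reduces to Pearson and obeys the identity", {
  set.seed(40)
  x <- rnorm(30); y <- 0.5 * x + rnorm(30)
  pc0 <- partial_correlation(x, y)
  expect_equal(pc0$r, cor(x, y), tolerance = 1e-12)
  expect_equal(pc0$p, cor.test(x, y)$p.value, tolerance = 1e-10)

  z <- rnorm(30)
  expect_equal(partial_correlation(x, x + 0 * z, z)$r, 1, tolerance = 1e-10)

  for (i in 1:100) {
    n <- sample(8:25, 1)
    z <- rnorm(n); x <- 0.4 * z + rnorm(n); y <- -0.3 * z + rnorm(n)
    pc <- partial_correlation(x, y, z)
    rxy <- cor(x, y); rxz <- cor(x, z); ryz <- cor(y, z)
    expect_equal(pc$r, (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2)),
                 tolerance = 1e-10)
    expect_equal(pc$df, n - 3)
  }
  expect_error(partial_correlation(1:3, 1:3, 1:3), "need n")
})

test_that("BH adjustment matches the brute-force step-up rule", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  brute_bh <- function(p) {
    m <- length(p); o <- order(p)
    q <- numeric(m)
    for (i in seq_len(m))
      q[o[i]] <- min(1, min(m * p[o][i:m] / (i:m)))
    q
  }
  set.seed(50)
  for (i in 1:100) {
    p <- runif(sample(1:20, 1))^sample(1:3, 1)
    expect_equal(bh_fdr(p), brute_bh(p), tolerance = 1e-12)
    ps <- sort(p)
    expect_true(!is.unsorted(bh_fdr(ps)))
  }
  expect_error(bh_fdr(c(0.2, 1.2)), "\\[0, 1\\]")
})

test_that("roc_analysis agrees with pROC on random data", {
  skip_if_not_installed("pROC")
  set.seed(60)
  for (i in 1:20) {
    n <- sample(10:30, 1)
    s <- rnorm(n); l <- rbinom(n, 1, 0.5)
    if (length(unique(l)) < 2) next
    mine <- roc_analysis(s, l)
    # pROC with a fixed direction; our AUC is the oriented max of the two
    a <- as.numeric(pROC::auc(suppressMessages(pROC::roc(l, s, direction = "<"))))
    expect_equal(mine$auc, max(a, 1 - a), tolerance = 1e-12)
  }
})
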