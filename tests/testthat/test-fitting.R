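test_that("normalize_and_average collapses directions correctly", {
  sch <- tiny_scheme()
  p <- fm_params(8e-4, 1.6, 0.45)
  att_cells <- matrix(fm_attenuation(p$D, p$alpha, p$hurst, sch,
                                     cells = scheme_cells(sch)), nrow = 1)
  vol <- signals_as_volume(cells_to_measurements(att_cells, sch), sch, S0 = 10)
  nm <- normalize_and_average(vol, sch)
  # identical directions -> averaged value equals that signal, to 10 digits
  expect_equal(as.vector(nm$attenuation), as.vector(att_cells),
               tolerance = 1e-10)

  # scaling one direction by k and another by 1/k leaves the geometric mean
  vol2 <- vol
  m <- sch$measurements
  k <- 1.7
  wx <- sch$n_b0 + which(m$direction == "x")
  wy <- sch$n_b0 + which(m$direction == "y")
  vol2[, , , wx] <- vol2[, , , wx] * k
  vol2[, , , wy] <- vol2[, , , wy] / k
  nm2 <- normalize_and_average(vol2, sch)
  expect_equal(nm2$attenuation, nm$attenuation, tolerance = 1e-12)

  # arithmetic option differs once directions disagree
  nm3 <- normalize_and_average(vol2, sch,
                               config = fm_fit_config(direction_average = "arithmetic"))
  expect_gt(max(abs(nm3$attenuation - nm$attenuation)), 0)

  expect_error(normalize_and_average(vol[, , , 1:5, drop = FALSE], sch),
               "does not match")
})

test_that("voxels with non-positive S0 are flagged unfittable, not fatal", {
  sch <- tiny_scheme()
  vol <- array(1, c(2, 1, 1, scheme_n_volumes(sch)))
  vol[2, 1, 1, seq_len(sch$n_b0)] <- 0
  nm <- normalize_and_average(vol, sch)
  expect_equal(nm$unfittable, c(FALSE, TRUE))
})

test_that("noiseless FM round-trip recovers parameters within 0.1%", {
  sch <- default_scheme()
  cells <- scheme_cells(sch)
  for (truth in list(c(5e-4, 1.55, 0.48), c(2e-4, 1.2, 0.65),
                     c(1.5e-3, 1.9, 0.35))) {
    att <- fm_attenuation(truth[1], truth[2], truth[3], sch, cells = cells)
    fit <- fit_fm_voxel(att, sch, cells = cells)
    expect_false(fit$unfittable)
    got <- c(fit$params$D, fit$params$alpha, fit$params$hurst)
    expect_true(all(abs(got / truth - 1) < 1e-3),
                info = paste(truth, collapse = "/"))
    expect_equal(fit$mu, memory_parameter(fit$params$alpha, fit$params$hurst))
  }
})

test_that("Gaussian-diffusion signals fit to the alpha boundary", {
  sch <- default_scheme()
  cells <- scheme_cells(sch)
  att <- fm_attenuation(1.1e-3, 2, 0.5, sch, cells = cells)
  fit <- fit_fm_voxel(att, sch, cells = cells)
  expect_gte(fit$params$alpha, 1.99)
})

test_that("degenerate attenuations are handled", {
  sch <- default_scheme()
  cells <- scheme_cells(sch)
  # constant S = S0: no decay, D driven to the lower bound
  fit <- fit_fm_voxel(rep(1, nrow(cells)), sch, cells = cells)
  expect_equal(fit$params$D, fm_fit_config()$bounds$D[1])
  expect_lt(fit$sse, 1e-12)
  # fewer than 3 usable observations
  fit2 <- fit_fm_voxel(c(0.5, 0.4, rep(NA, nrow(cells) - 2)), sch, cells = cells)
  expect_true(fit2$unfittable)
})

test_that("with alpha, H frozen the fit matches log-linear regression", {
  sch <- default_scheme()
  cells <- scheme_cells(sch)
  adc <- 9e-4
  b_np <- sch$gamma^2 * cells$G0^2 * sch$delta^2 * cells$Delta * 1e-6
  att <- exp(-b_np * adc)
  cfg <- fm_fit_config(bounds = list(D = c(1e-8, 10), alpha = c(2, 2),
                                     hurst = c(0.5, 0.5)),
                       init_alpha = 2, init_hurst = 0.5)
  fit <- fit_fm_voxel(att, sch, cells = cells, config = cfg)
  d_lm <- -coef(lm(log(att) ~ b_np + 0))[[1]]
  expect_equal(fit$params$D / d_lm, 1, tolerance = 1e-6)
})

test_that("compute_adc inverts the mono-exponential model", {
  expect_equal(compute_adc(2, 2, 900), 0)
  adc <- compute_adc(1, exp(-954 * 0.00108), 954)
  expect_equal(adc, 0.00108)
  expect_equal(signif(compute_adc(1, 0.3569, 954), 3), 0.00108)
  expect_true(is.na(compute_adc(0, 0.5, 900)))
  expect_error(compute_adc(1, 0.5, -1), "b1")
})

test_that("the ADC cell is the one nearest the configured target b", {
  sch <- default_scheme()
  cells <- scheme_cells(sch)
  ci <- fmdiff:::.adc_cell_index(cells, 954)
  expect_equal(round(cells$bvalue[ci]), 964)  # 964 is nearer 954 than 939
  # tie resolves to the lower b
  ct <- data.frame(bvalue = c(100, 300), Delta = 1, G0 = 1)
  expect_equal(fmdiff:::.adc_cell_index(ct, 200), 1)
})

test_that("volume fitting fills maps only inside the mask, mu derived exactly", {
  sch <- default_scheme()
  cells <- scheme_cells(sch)
  regions <- list(A = c(6e-4, 1.58, 0.46), B = c(1.1e-3, 1.52, 0.48))
  att <- rbind(fm_attenuation(regions$A[1], regions$A[2], regions$A[3], sch, cells = cells),
               fm_attenuation(regions$B[1], regions$B[2], regions$B[3], sch, cells = cells))
  att_m <- cells_to_measurements(att, sch)
  # 4x4x1 phantom, region A in the left half, B in the right
  vol <- array(0, c(4, 4, 1, scheme_n_volumes(sch)))
  for (x in 1:4) for (y in 1:4) {
    row <- if (x <= 2) 1 else 2
    vol[x, y, 1, ] <- c(rep(1, sch$n_b0), att_m[row, ])
  }
  mask <- array(TRUE, c(4, 4, 1))
  mask[1, 1, 1] <- FALSE
  maps <- fit_fm_volume(vol, mask, sch)
  expect_true(is.na(maps$alpha[1, 1, 1]))
  expect_equal(maps$qc$n_fitted, 15)
  for (x in 1:4) for (y in 1:4) {
    if (x == 1 && y == 1) next
    truth <- if (x <= 2) regions$A else regions$B
    expect_equal(maps$alpha[x, y, 1] / truth[2], 1, tolerance = 1e-3)
    expect_equal(maps$hurst[x, y, 1] / truth[3], 1, tolerance = 1e-3)
    expect_equal(maps$D[x, y, 1] / truth[1], 1, tolerance = 1e-3)
  }
  idx <- !is.na(maps$mu)
  expect_identical(maps$mu[idx],
                   maps$hurst[idx] - 1 / maps$alpha[idx])

  empty <- fit_fm_volume(vol, array(FALSE, c(4, 4, 1)), sch)
  expect_equal(empty$qc$n_fitted, 0)
  expect_true(all(is.na(empty$alpha)))
  expect_error(fit_fm_volume(vol, array(TRUE, c(3, 3, 1)), sch), "mask")
})

test_that("volume fitting is deterministic", {
  sch <- default_scheme()
  set.seed(11)
  att <- matrix(runif(3 * 18, 0.2, 1), nrow = 3)
  vol <- signals_as_volume(cells_to_measurements(att, sch), sch)
  m1 <- fit_fm_volume(vol, NULL, sch)
  m2 <- fit_fm_volume(vol, NULL, sch)
  expect_identical(m1$alpha, m2$alpha)
  expect_identical(m1$D, m2$D)
  expect_identical(m1$adc, m2$adc)
})
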