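fs <- 5
prot <- protocol_spec()
hrf <- hrf_spec()

test_that("design matrix has a unit-peak task column plus a constant", {
  X <- build_design(prot, hrf, fs)
  expect_equal(max(X$X[, "task"]), 1)
  expect_true(all(X$X[, "constant"] == 1))
  expect_equal(X$n_samples, 2900)
  # task column is the unit-amplitude task component
  tc <- make_task_component(build_boxcar(prot, fs), sample_hrf(hrf, fs), 1)
  expect_equal(X$X[, "task"], tc$values, ignore_attr = TRUE)
  expect_lt(abs(cor(X$X[, "task"], rep(1, X$n_samples) + rnorm(X$n_samples, 0, 1e-12))), 1)
  expect_error(build_design(prot, hrf, fs, n_samples = 1234), "does not match")
})

test_that("OLS fit matches the normal-equations oracle and recovers exact signals", {
  X <- build_design(prot, hrf, fs)
  f <- fit_ols(8e-7 * X$X[, "task"], X)
  expect_equal(f$beta_task, 8e-7, tolerance = 1e-12)
  expect_equal(f$beta_const, 0, tolerance = 1e-18)

  f2 <- fit_ols(rep(3.2e-7, X$n_samples), X)
  expect_equal(f2$beta_task, 0, tolerance = 1e-18)
  expect_equal(f2$beta_const, 3.2e-7, tolerance = 1e-12)
  expect_equal(f2$dof, X$n_samples - 2L)

  set.seed(42)
  y <- rnorm(X$n_samples, 0, 1e-6)
  f3 <- fit_ols(y, X)
  hand <- ols_normal_equations(X$X, y)
  expect_equal(f3$beta_task, hand[1], tolerance = 1e-10)
  expect_equal(f3$beta_const, hand[2], tolerance = 1e-10)
  # residual orthogonality to the design
  expect_lt(abs(sum(f3$residuals * X$X[, "task"])) /
              (sqrt(sum(f3$residuals^2)) * sqrt(sum(X$X[, "task"]^2))), 1e-8)
  expect_lt(abs(sum(f3$residuals)) /
              (sqrt(sum(f3$residuals^2)) * sqrt(X$n_samples)), 1e-8)

  # scale equivariance
  f4 <- fit_ols(3 * y, X)
  expect_equal(f4$beta_task, 3 * f3$beta_task, tolerance = 1e-12)

  expect_error(fit_ols(c(y[-1], NA), X), "non-finite")
})

test_that("precoloring preserves constants, keeps exact recovery, and imposes a known residual structure", {
  X <- build_design(prot, hrf, fs)
  k <- sample_hrf(hrf, fs)
  pc <- precolor(rep(1, X$n_samples), X, k)
  expect_equal(pc$X$X[, "constant"], rep(1, X$n_samples),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(pc$y, rep(1, X$n_samples), tolerance = 1e-12)

  # noise-free: same beta after precoloring
  y <- 8e-7 * X$X[, "task"]
  pc2 <- precolor(y, X, k)
  f <- fit_ols(pc2$y, pc2$X, "precolor")
  expect_equal(f$beta_task, 8e-7, tolerance = 1e-10 * 8e-7)

  # the precolored residual autocorrelation is dominated by the smoothing
  # kernel: it is high and nearly independent of the noise AR coefficient,
  # while the uncorrected residual autocorrelation tracks it
  ac1 <- function(r) cor(r[-1], r[-length(r)])
  res <- sapply(1:20, function(s) {
    set.seed(s)
    out <- c()
    for (phi in c(0.3, 0.7)) {
      e <- as.numeric(stats::arima.sim(list(ar = phi), X$n_samples)) * 1e-7
      yy <- 8e-7 * X$X[, "task"] + e
      f0 <- fit_ols(yy, X, "none")
      p <- precolor(yy, X, k)
      f1 <- fit_ols(p$y, p$X, "precolor")
      out <- c(out, ac1(f0$residuals), ac1(f1$residuals))
    }
    out  # none.3, pre.3, none.7, pre.7
  })
  m <- rowMeans(res)
  expect_gt(m[2], 0.95)                     # kernel-dominated
  expect_gt(m[4], 0.95)
  expect_lt(abs(m[4] - m[2]), 0.1 * (m[3] - m[1]))  # insensitive to phi
  expect_gt(m[3] - m[1], 0.2)               # uncorrected tracks phi
})

test_that("spline down-sampling is exact on polynomials and accurate on slow tones", {
  s <- channel_series(rep(4.2, 500), fs, "HbO2")
  d <- downsample_spline(s, fs_new = 1)
  expect_true(all(abs(d$values - 4.2) < 1e-12))
  expect_equal(d$fs, 1)

  ramp <- channel_series(seq(0, 1, length.out = 500), fs, "HbO2")
  dr <- downsample_spline(ramp, fs_new = 1)
  t_new <- seq(0, 499 / fs, by = 1)
  expect_equal(dr$values, t_new / (499 / fs), tolerance = 1e-12)

  t <- (0:2899) / fs
  tone <- channel_series(sin(2 * pi * 0.05 * t), fs, "HbO2")
  dt <- downsample_spline(tone, fs_new = 1)
  t1 <- seq(0, max(t), by = 1)
  expect_lt(max(abs(dt$values - sin(2 * pi * 0.05 * t1))), 1e-3)

  expect_error(downsample_spline(s, fs_new = 10), "smaller")
})

test_that("noise-free beta recovery is exact under all three corrections", {
  amps <- amplitude_presets()$Amplitude1
  tc <- make_task_component(build_boxcar(prot, fs), sample_hrf(hrf, fs),
                            amps$hbo2_amp)
  for (corr in c("none", "downsample", "precolor")) {
    f <- fit_glm_corrected(tc, prot, hrf, corr)
    expect_lt(abs(f$beta_task - amps$hbo2_amp) / amps$hbo2_amp, 1e-10)
    expect_identical(f$correction, corr)
  }
})
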