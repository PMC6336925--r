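test_that("FIR designs are linear phase with the stated gain conventions", {
  lp4 <- design_filter(filter_spec("LP", "FIR", 4, fc_high = 0.1))
  expect_length(lp4$b, 5)
  expect_equal(lp4$b, rev(lp4$b), tolerance = 1e-12)  # symmetric
  expect_equal(sum(lp4$b), 1, tolerance = 1e-14)       # unit DC gain

  bp <- design_filter(filter_spec("BP", "FIR", 100, 0.01, 0.2))
  expect_equal(bp$b, rev(bp$b), tolerance = 1e-12)
  expect_equal(bp$group_delay, 50)

  ma <- design_filter(filter_spec("LP", "MovAvg", fc_high = 0.1))
  expect_true(all(abs(ma$b - 1 / length(ma$b)) < 1e-15))
  expect_error(filter_spec("BP", "MovAvg", 3, 0.01, 0.1), "low-pass only")
})

test_that("Butterworth coefficients match an independent bilinear-transform oracle", {
  co <- design_filter(filter_spec("LP", "BW", 3, fc_high = 0.5, fs = 5))
  oracle <- butter_lp_bilinear(3, 0.5, 5)
  expect_equal(co$a / co$a[1], oracle$a / oracle$a[1], tolerance = 1e-9)
  expect_equal(co$b / co$a[1], oracle$b / oracle$a[1], tolerance = 1e-9)
})

test_that("z-plane stability matches the study's classification", {
  stable5 <- check_stability(design_filter(filter_spec("BP", "BW", 5, 0.01, 0.2)))
  expect_true(stable5$is_stable)
  unstable20 <- check_stability(design_filter(filter_spec("BP", "BW", 20, 0.01, 0.2)))
  expect_false(unstable20$is_stable)
  # FIR and MovAvg always stable
  expect_true(check_stability(design_filter(filter_spec("BP", "FIR", 1000, 0.01, 0.09)))$is_stable)
  expect_true(check_stability(design_filter(filter_spec("LP", "MovAvg", fc_high = 0.1)))$is_stable)
})

test_that("zero-phase application introduces no lag and handles band edges", {
  fs <- 5
  n <- 2900
  x <- channel_series(sin(2 * pi * 0.05 * (0:(n - 1)) / fs), fs, "HbO2")
  for (spec in list(filter_spec("BP", "BW", 3, 0.01, 0.09),
                    filter_spec("BP", "FIR", 1000, 0.01, 0.09),
                    filter_spec("BP", "FIR", 5, 0.01, 0.09))) {
    y <- apply_filter(design_filter(spec), x)
    cc <- stats::ccf(y$values, x$values, lag.max = 10, plot = FALSE)
    expect_equal(cc$lag[which.max(cc$acf)], 0)
    expect_length(y$values, n)
  }

  z <- channel_series(rep(0, 500), fs, "HbO2")
  co <- design_filter(filter_spec("BP", "BW", 3, 0.01, 0.2))
  expect_true(all(apply_filter(co, z)$values == 0))

  # DC offset: removed by BP, passed by LP
  dc <- channel_series(rep(2, n), fs, "HbO2")
  expect_lt(abs(mean(apply_filter(co, dc)$values)), 0.01 * 2)
  lp <- design_filter(filter_spec("LP", "BW", 3, fc_high = 0.1))
  expect_equal(mean(apply_filter(lp, dc)$values), 2, tolerance = 1e-6)

  # refusing unstable IIR
  bad <- design_filter(filter_spec("BP", "BW", 20, 0.01, 0.2))
  err <- tryCatch(apply_filter(bad, x), error = identity)
  expect_s3_class(err$stability_report, "stability_report")
})

test_that("amplitude response reflects the realized (forward-backward) filtering", {
  rec <- design_filter(filter_spec("BP", "FIR", 1000, 0.01, 0.09))
  ar <- amplitude_response(rec, 4096)
  g_stim <- stats::approx(ar$freq, ar$magnitude, 0.025)$y
  expect_lt(abs(20 * log10(g_stim)), 0.1)  # flat passband at f_stim
  g_cardiac <- stats::approx(ar$freq, ar$magnitude, 1)$y
  expect_lt(20 * log10(g_cardiac), -40)

  ma <- design_filter(filter_spec("LP", "MovAvg", fc_high = 0.1))
  expect_equal(amplitude_response(ma, 64)$magnitude[1], 1)

  # IIR response is squared: realized gain at fc is -6 dB, not -3 dB
  bw <- design_filter(filter_spec("LP", "BW", 3, fc_high = 0.5))
  g_fc <- stats::approx(amplitude_response(bw, 4096)$freq,
                        amplitude_response(bw, 4096)$magnitude, 0.5)$y
  expect_equal(20 * log10(g_fc), -6.02, tolerance = 0.05)
})

test_that("Kaiser order estimate follows the published formula", {
  # hand evaluation: N = (A - 7.95) / (2.285 * 2 pi df / fs)
  hand <- (60 - 7.95) / (2.285 * 2 * pi * 0.01 / 5)
  expect_equal(estimate_fir_order_kaiser(0.01, 5, 60),
               as.integer(2 * ceiling(hand / 2)))
  # inverse proportionality in the transition width
  n1 <- estimate_fir_order_kaiser(0.02, 5, 60)
  n2 <- estimate_fir_order_kaiser(0.01, 5, 60)
  expect_gte(n2, 2 * n1 - 4)
  # monotone in stopband attenuation
  expect_gte(estimate_fir_order_kaiser(0.01, 5, 80),
             estimate_fir_order_kaiser(0.01, 5, 40))
})

test_that("Welch PSD matches a direct-DFT periodogram and locates tones", {
  fs <- 5
  t <- (0:599) / fs
  x <- sin(2 * pi * 0.1 * t)
  # single segment: welch with window = full length equals the direct DFT
  w <- welch_psd(x, fs = fs, window_s = 120, overlap = 0.5)
  seg <- x[1:600]
  expect_warning(w1 <- welch_psd(seg[1:300], fs = fs, window_s = 120),
                 "single")
  direct <- periodogram_direct(seg[1:300], fs)
  expect_equal(w1$psd, direct$psd, tolerance = 1e-10)
  expect_equal(w1$freq, direct$freq)

  expect_equal(w$freq[which.max(w$psd)], 0.1, tolerance = 1 / 120 + 1e-9)
  z <- welch_psd(rep(0, 700), fs = fs)
  expect_true(all(z$psd == 0))
})

test_that("the full Butterworth stability grid reproduces the reported pattern", {
  fs <- 5
  # band-pass: orders 3-4 stable everywhere; 5 only for upper edges
  # >= 0.2 Hz; >= 20 never
  truth_bp <- function(ord, hi) ord <= 4 || (ord == 5 && hi >= 0.2)
  for (hi in c(0.09, 0.2, 0.3, 0.5)) {
    for (ord in c(3, 4, 5, 20, 100, 200, 500, 1000)) {
      s <- check_stability(design_filter(filter_spec("BP", "BW", ord, 0.01, hi)))
      expect_identical(s$is_stable, truth_bp(ord, hi),
                       label = sprintf("BP order %d fc [0.01, %g]", ord, hi))
    }
  }
  # low-pass: orders 3-5 stable everywhere; 20 only at 0.5 Hz; >= 100 never
  truth_lp <- function(ord, fc) ord <= 5 || (ord == 20 && fc == 0.5)
  for (fc in c(0.09, 0.1, 0.14, 0.5)) {
    for (ord in c(3, 4, 5, 20, 100, 200, 500, 1000)) {
      s <- check_stability(design_filter(filter_spec("LP", "BW", ord, fc_high = fc)))
      expect_identical(s$is_stable, truth_lp(ord, fc),
                       label = sprintf("LP order %d fc %g", ord, fc))
    }
  }
})
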