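test_that("boxcar construction matches the block design exactly", {
  p <- protocol_spec(14, 20, 20, lead_in = 20)
  expect_equal(p$f_stim, 0.025)
  b <- build_boxcar(p, fs = 5)
  expect_length(b$values, 2900)
  expect_equal(sum(b$values), 14 * 100)
  expect_true(all(b$values %in% c(0, 1)))
  # first block starts exactly at the lead-in
  expect_equal(b$values[100], 0)
  expect_equal(b$values[101], 1)
  # duty cycle is exact in sample counts
  post_lead <- b$values[-(1:100)]
  expect_equal(mean(post_lead), 20 / (20 + 20))

  b1 <- build_boxcar(protocol_spec(1, 20, 20, 0), fs = 1)
  expect_equal(b1$values, c(rep(1, 20), rep(0, 20)))

  expect_error(protocol_spec(14, -1, 20), "positive")
})

test_that("double-gamma HRF peaks at 6 s and troughs at 16 s", {
  h <- hrf_spec()
  k <- sample_hrf(h, fs = 5)
  t <- seq(0, h$kernel_duration, by = 1 / 5)
  expect_equal(t[which.max(k)], 6.0)
  expect_equal(t[which.min(k)], 16.0)
  expect_equal(k[1], 0)
  expect_equal(max(k), 1)
  # alternate parameterizations keep the promised extrema
  h2 <- hrf_spec(peak_time = 5, undershoot_time = 14, kernel_duration = 30)
  k2 <- sample_hrf(h2, fs = 10)
  t2 <- seq(0, 30, by = 0.1)
  expect_lt(abs(t2[which.max(k2)] - 5), 0.1 + 1e-9)
  expect_lt(abs(t2[which.min(k2)] - 14), 0.1 + 1e-9)
  expect_error(hrf_spec(kernel_duration = 10), "kernel_duration")
})

test_that("task component scales to the generating amplitude and matches a brute-force convolution", {
  p <- small_protocol()
  h <- hrf_spec()
  b <- build_boxcar(p, 5)
  k <- sample_hrf(h, 5)
  amp <- 8e-7
  tc <- make_task_component(b, k, amp)
  expect_equal(max(tc$values), amp)

  tc0 <- make_task_component(b, k, 0)
  expect_true(all(tc0$values == 0))

  # package convolution vs O(n m) sum
  direct <- conv_bruteforce(b$values, k)
  pkg <- make_task_component(b, k, 1)$values * max(abs(direct))
  expect_equal(pkg, direct, tolerance = 1e-12)
})

test_that("task component concentrates power at the stimulation frequency", {
  p <- protocol_spec()
  tc <- make_task_component(build_boxcar(p, 5), sample_hrf(hrf_spec(), 5), 1)
  X <- Mod(stats::fft(tc$values))
  n <- length(X)
  freqs <- (seq_len(n) - 1) * 5 / n
  half <- 2:floor(n / 2)  # skip DC
  f_at_max <- freqs[half][which.max(X[half])]
  expect_lt(abs(f_at_max - p$f_stim), 5 / n + 1e-12)  # within one DFT bin
})

test_that("amplitude presets keep the HbR/HbO2 ratio near -1/3", {
  for (a in amplitude_presets()) {
    r <- a$hbr_amp / a$hbo2_amp
    expect_gte(r, -0.35)
    expect_lte(r, -0.30)
  }
  expect_error(amplitude_spec(-1e-7, -1e-7), "hbo2_amp")
  expect_error(amplitude_spec(1e-7, 1e-7), "hbr_amp")
})

test_that("resting-pair simulation is seeded, spectrally structured, and silent when zeroed", {
  ns <- noise_spec()
  a <- simulate_resting_pair(ns, 580, 5, seed = 123)
  b <- simulate_resting_pair(ns, 580, 5, seed = 123)
  expect_identical(a$hbo2$values, b$hbo2$values)
  expect_identical(a$hbr$values, b$hbr$values)
  c <- simulate_resting_pair(ns, 580, 5, seed = 124)
  expect_false(identical(a$hbo2$values, c$hbo2$values))

  z <- simulate_resting_pair(silent_noise_spec(), 580, 5, seed = 1)
  expect_true(all(z$hbo2$values == 0))
  expect_true(all(z$hbr$values == 0))

  # cardiac peak: PSD argmax over [0.8, 1.5] Hz within 0.1 Hz of the
  # subject's drawn cardiac frequency (reconstructed from the same seed)
  w <- welch_psd(a$hbo2)
  sel <- w$freq >= 0.8 & w$freq <= 1.5
  f_peak <- w$freq[sel][which.max(w$psd[sel])]
  set.seed(123)
  cmp <- ns$components
  f_drawn <- stats::rnorm(nrow(cmp), cmp$center_freq, cmp$freq_jitter_sd)[1]
  expect_lt(abs(f_peak - f_drawn), 0.1)
})

test_that("subject channels share systemic rhythms but are not copies", {
  chans <- simulate_subject_channels(noise_spec(), 4, 580, 5, seed = 9)
  expect_length(chans, 4)
  v1 <- chans[[1]]$hbo2$values
  v2 <- chans[[2]]$hbo2$values
  expect_false(identical(v1, v2))
  # common systemic noise: channels substantially correlated
  expect_gt(cor(v1, v2), 0.5)
})

test_that("dataset assembly produces 3 datasets x subjects x channels with a shared task", {
  ds <- assemble_dataset(n_subjects = 2, n_channels = 1,
                         protocol = small_protocol(), master_seed = 5)
  expect_named(ds, c("Amplitude1", "Amplitude2", "Amplitude3"))
  expect_length(ds$Amplitude1, 2)
  expect_length(ds$Amplitude1[[1]]$channels, 1)

  # identical task component across channels within a subject: difference
  # of two channels contains no task (only noise), while the difference
  # across amplitude presets of the same channel is exactly the task delta
  ds2 <- assemble_dataset(n_subjects = 2, n_channels = 3,
                          protocol = small_protocol(), master_seed = 5)
  a1 <- ds2$Amplitude1[[1]]
  a2 <- ds2$Amplitude2[[1]]
  delta <- a1$channels[[1]]$hbo2$values - a2$channels[[1]]$hbo2$values
  delta2 <- a1$channels[[3]]$hbo2$values - a2$channels[[3]]$hbo2$values
  expect_equal(delta, delta2, tolerance = 1e-12)
  amps <- amplitude_presets()
  expect_equal(max(delta), amps$Amplitude1$hbo2_amp - amps$Amplitude2$hbo2_amp,
               tolerance = 1e-9)

  # same master seed -> identical; different -> different noise, same task
  ds3 <- assemble_dataset(n_subjects = 2, n_channels = 1,
                          protocol = small_protocol(), master_seed = 5)
  expect_identical(ds$Amplitude1[[1]]$channels[[1]]$hbo2$values,
                   ds3$Amplitude1[[1]]$channels[[1]]$hbo2$values)
  ds4 <- assemble_dataset(n_subjects = 2, n_channels = 1,
                          protocol = small_protocol(), master_seed = 6)
  expect_false(identical(ds$Amplitude1[[1]]$channels[[1]]$hbo2$values,
                         ds4$Amplitude1[[1]]$channels[[1]]$hbo2$values))
  expect_error(assemble_dataset(n_subjects = 1, master_seed = 1), "n_subjects")
})

test_that("motion artifact injection is additive and localized", {
  s <- channel_series(rep(0, 500), 5, "HbO2")
  expect_identical(inject_motion_artifacts(s, NULL)$values, s$values)

  ev <- data.frame(time = 50, type = "shift", magnitude = 1e-6)
  shifted <- inject_motion_artifacts(s, ev)
  expect_equal(mean(shifted$values[252:500]) - mean(shifted$values[1:250]),
               1e-6, tolerance = 1e-12)
  expect_identical(shifted$values[1:250], s$values[1:250])

  ev2 <- data.frame(time = 50, type = "spike", magnitude = 1e-6)
  spiked <- inject_motion_artifacts(s, ev2)
  expect_equal(max(spiked$values), 1e-6)
  expect_lt(spiked$values[251 + 25], 1e-6 * exp(-24 / 2.5) + 1e-18)
})
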