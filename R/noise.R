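#' Physiological noise model for synthetic resting-state fNIRS
#'
#' Resting-state concentration noise is modelled with the structure of real
#' multi-channel recordings:
#'
#' * narrow-band systemic oscillators (cardiac ~1.1 Hz, respiration
#'   ~0.3 Hz, Mayer waves ~0.095 Hz, very-low-frequency activity ~0.02 Hz)
#'   whose frequency, base amplitude and phase are drawn per subject and
#'   shared across channels, with per-channel amplitude scaling and small
#'   phase lags — systemic physiology is common to all channels, which is
#'   why a median over channels does not average it away;
#' * a baseline settling trend `A (1 - exp(-t / settle_tau))` with
#'   subject-varying amplitude of consistent average direction, emulating
#'   the slow monotone drifts (probe coupling and superficial blood volume
#'   settling) that make unfiltered low-frequency content inflate GLM
#'   estimates;
#' * a smoothed random-walk drift split into a channel-common and a
#'   channel-specific part; and
#' * white measurement noise, independent per channel.
#'
#' All amplitudes are in Molar. The HbR realization shares the subject's
#' rhythms at `hbr_scale` of the HbO2 amplitude with independent oscillator
#' phases, and carries the settling trend and common drift anti-correlated
#' with HbO2 (scaled by `-hbr_scale`), the typical resting relationship
#' between the chromophores.
#'
#' @param components data frame with columns `name`, `center_freq` (Hz),
#'   `freq_jitter_sd` (Hz), `amplitude` (Molar), `amplitude_jitter_sd`
#'   (Molar)
#' @param drift_amp RMS amplitude of the random-walk drift, Molar
#' @param drift_timescale smoothing time-scale of the drift, seconds
#' @param drift_channel_frac channel-specific drift RMS as a fraction of
#'   `drift_amp` (the rest is channel-common)
#' @param settle_amp mean amplitude of the settling trend, Molar
#' @param settle_sd between-subject SD of the settling amplitude, Molar
#' @param settle_tau settling time constant, seconds
#' @param white_sd white measurement-noise SD, Molar
#' @param hbr_scale attenuation of the HbR realization relative to HbO2,
#'   in (0, 1]
#' @param chan_amp_sd per-channel oscillator amplitude scaling SD
#'   (around 1)
#' @param chan_phase_sd per-channel oscillator phase lag SD, radians
#' @return a `noise_spec`
#' @export
noise_spec <- function(components = default_noise_components(),
                       drift_amp = uMol(0.8), drift_timescale = 60,
                       drift_channel_frac = 0.5,
                       settle_amp = uMol(0.5), settle_sd = uMol(0.3),
                       settle_tau = 120,
                       white_sd = uMol(0.05), hbr_scale = 1 / 3,
                       chan_amp_sd = 0.2, chan_phase_sd = 0.3) {
  stopifnot(is.data.frame(components),
            all(c("center_freq", "freq_jitter_sd", "amplitude",
                  "amplitude_jitter_sd") %in% names(components)))
  if (any(components$freq_jitter_sd < 0) ||
      any(components$amplitude_jitter_sd < 0) ||
      white_sd < 0 || drift_amp < 0 || settle_sd < 0)
    stop("all noise SDs and amplitudes must be >= 0")
  if (!(hbr_scale > 0 && hbr_scale <= 1))
    stop("hbr_scale must be in (0, 1]")
  structure(
    list(components = components, drift_amp = drift_amp,
         drift_timescale = drift_timescale,
         drift_channel_frac = drift_channel_frac,
         settle_amp = settle_amp, settle_sd = settle_sd,
         settle_tau = settle_tau,
         white_sd = white_sd, hbr_scale = hbr_scale,
         chan_amp_sd = chan_amp_sd, chan_phase_sd = chan_phase_sd),
    class = "noise_spec"
  )
}

#' Default physiological noise bands
#'
#' @return data frame of the four default oscillatory components
#' @export
default_noise_components <- function() {
  data.frame(
    name = c("cardiac", "respiration", "mayer", "vlf"),
    center_freq = c(1.1, 0.3, 0.095, 0.02),
    freq_jitter_sd = c(0.15, 0.05, 0.01, 0.01),
    amplitude = uMol(c(0.4, 0.2, 0.3, 0.3)),
    amplitude_jitter_sd = uMol(c(0.12, 0.06, 0.09, 0.09)),
    stringsAsFactors = FALSE
  )
}

#' A zeroed noise specification
#'
#' All oscillator, drift, settling and white-noise amplitudes set to zero;
#' useful for noise-free pipeline checks.
#'
#' @return a `noise_spec` generating identically zero series
#' @export
silent_noise_spec <- function() {
  cmp <- default_noise_components()
  cmp$amplitude <- 0
  cmp$amplitude_jitter_sd <- 0
  noise_spec(components = cmp, drift_amp = 0, settle_amp = 0,
             settle_sd = 0, white_sd = 0)
}

# smoothed random-walk drift scaled to unit RMS (zero if degenerate)
smoothed_drift <- function(n, fs, timescale) {
  w <- stats::rnorm(n)
  rw <- cumsum(w)
  L <- max(3L, seconds_to_samples(timescale, fs))
  k <- rep(1 / L, L)
  pad <- c(rev(rw[seq_len(min(L, n))]), rw, rev(rw)[seq_len(min(L, n))])
  sm <- stats::filter(pad, k, sides = 2)
  sm <- as.numeric(sm)[min(L, n) + seq_len(n)]
  sm <- sm - mean(sm)
  r <- sqrt(mean(sm^2))
  if (r > 0) sm / r else sm * 0
}

#' Simulate one subject's correlated multi-channel noise
#'
#' Deterministic given `seed`. Subject-level draws (oscillator frequencies,
#' base amplitudes and phases, settling amplitude, common drift) are shared
#' across channels; channel-level draws (amplitude scalings, phase lags,
#' channel drift, white noise) differ per channel.
#'
#' @param noise a [noise_spec()]
#' @param n_channels number of channels
#' @param duration record length, seconds
#' @param fs sampling rate, Hz
#' @param seed integer seed
#' @return list of `n_channels` elements, each
#'   `list(hbo2 = <channel_series>, hbr = <channel_series>)`
#' @export
simulate_subject_channels <- function(noise, n_channels, duration, fs, seed) {
  stopifnot(inherits(noise, "noise_spec"))
  n <- seconds_to_samples(duration, fs)
  if (n < 2L) stop("duration too short at fs")
  if (duration < 2 * noise$drift_timescale)
    warning("record shorter than twice the drift timescale; ",
            "drift is poorly resolved")
  t <- (seq_len(n) - 1L) / fs
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  cmp <- noise$components
  nc <- nrow(cmp)
  # subject-level physiology
  freqs <- stats::rnorm(nc, cmp$center_freq, cmp$freq_jitter_sd)
  freqs <- pmin(pmax(freqs, 1e-4), fs / 2 - 1e-6)
  amps <- pmax(0, stats::rnorm(nc, cmp$amplitude, cmp$amplitude_jitter_sd))
  ph_hbo2 <- stats::runif(nc, 0, 2 * pi)
  ph_hbr <- stats::runif(nc, 0, 2 * pi)
  settle_A <- stats::rnorm(1, noise$settle_amp, noise$settle_sd)
  settle <- settle_A * (1 - exp(-t / noise$settle_tau))
  common_drift <- noise$drift_amp * (1 - noise$drift_channel_frac) *
    smoothed_drift(n, fs, noise$drift_timescale)
  carriers <- lapply(seq_len(nc), function(i) 2 * pi * freqs[i] * t)

  out <- vector("list", n_channels)
  for (ch in seq_len(n_channels)) {
    scale_ch <- pmax(0.2, stats::rnorm(nc, 1, noise$chan_amp_sd))
    lag_ch <- stats::rnorm(nc, 0, noise$chan_phase_sd)
    trend_scale <- max(0.2, stats::rnorm(1, 1, noise$chan_amp_sd))
    hbo2 <- numeric(n)
    hbr <- numeric(n)
    for (i in seq_len(nc)) {
      a <- amps[i] * scale_ch[i]
      hbo2 <- hbo2 + a * sin(carriers[[i]] + ph_hbo2[i] + lag_ch[i])
      hbr <- hbr + noise$hbr_scale * a *
        sin(carriers[[i]] + ph_hbr[i] + lag_ch[i])
    }
    chan_drift <- noise$drift_amp * noise$drift_channel_frac *
      smoothed_drift(n, fs, noise$drift_timescale)
    slow <- trend_scale * settle + common_drift + chan_drift
    hbo2 <- hbo2 + slow + stats::rnorm(n, 0, noise$white_sd)
    hbr <- hbr - noise$hbr_scale * slow + stats::rnorm(n, 0, noise$white_sd)
    out[[ch]] <- list(hbo2 = channel_series(hbo2, fs, "HbO2"),
                      hbr = channel_series(hbr, fs, "HbR"))
  }
  out
}

#' Simulate a single resting-state (HbO2, HbR) concentration pair
#'
#' The single-channel case of [simulate_subject_channels()]: deterministic
#' given `seed`; the HbR series shares the subject's oscillator
#' frequencies with independent phases, attenuated by `hbr_scale`.
#'
#' @param noise a [noise_spec()]
#' @param duration record length, seconds
#' @param fs sampling rate, Hz
#' @param seed integer seed
#' @return list with `hbo2` and `hbr` [channel_series()] (Molar)
#' @export
simulate_resting_pair <- function(noise, duration, fs, seed) {
  simulate_subject_channels(noise, 1L, duration, fs, seed)[[1L]]
}

#' Inject motion artifacts into a series
#'
#' `spike` adds a one-sample-rise transient that decays exponentially
#' (time constant `decay_s`); `shift` adds a step from the event time to the
#' end of the record. Overlapping events add. Untouched samples are
#' bit-identical to the input.
#'
#' @param series a [channel_series()]
#' @param events data frame with columns `time` (s), `type`
#'   (`"spike"`/`"shift"`), `magnitude` (signal units)
#' @param decay_s spike decay time constant, seconds
#' @return the series with artifacts added
#' @export
inject_motion_artifacts <- function(series, events, decay_s = 0.5) {
  stopifnot(inherits(series, "channel_series"))
  if (is.null(events) || nrow(events) == 0L) return(series)
  n <- length(series$values)
  v <- series$values
  for (i in seq_len(nrow(events))) {
    i0 <- seconds_to_samples(events$time[i], series$fs) + 1L
    if (i0 < 1L || i0 > n) stop("event time outside the record")
    idx <- i0:n
    if (events$type[i] == "spike") {
      tau <- decay_s * series$fs
      v[idx] <- v[idx] + events$magnitude[i] * exp(-(idx - i0) / tau)
    } else if (events$type[i] == "shift") {
      v[idx] <- v[idx] + events$magnitude[i]
    } else stop("unknown event type: ", events$type[i])
  }
  series_with_values(series, v)
}
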