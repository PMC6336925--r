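#' Block-design stimulation protocol
#'
#' Defines a periodic block design: an initial lead-in rest, then `n_blocks`
#' repetitions of (task, rest). The implied stimulation frequency is
#' `f_stim = 1 / (task_dur + rest_dur)`; for the default 20 s / 20 s design
#' this is 0.025 Hz.
#'
#' @param n_blocks number of task blocks (>= 1)
#' @param task_dur task block duration, seconds
#' @param rest_dur rest duration between blocks, seconds
#' @param lead_in rest before the first block, seconds
#' @return a `protocol_spec` with fields `n_blocks`, `task_dur`, `rest_dur`,
#'   `lead_in`, `f_stim` (Hz) and `total_dur` (s)
#' @export
protocol_spec <- function(n_blocks = 14, task_dur = 20, rest_dur = 20,
                          lead_in = 20) {
  if (n_blocks < 1) stop("n_blocks must be >= 1")
  if (task_dur <= 0 || rest_dur <= 0 || lead_in < 0)
    stop("protocol durations must be positive (lead_in may be 0)")
  structure(
    list(n_blocks = as.integer(n_blocks), task_dur = task_dur,
         rest_dur = rest_dur, lead_in = lead_in,
         f_stim = 1 / (task_dur + rest_dur),
         total_dur = lead_in + n_blocks * (task_dur + rest_dur)),
    class = "protocol_spec"
  )
}

# seconds -> sample count, round half up (ties away from zero for positives)
seconds_to_samples <- function(x, fs) as.integer(floor(x * fs + 0.5))

#' Boxcar task indicator for a protocol
#'
#' Unit-less 0/1 series at rate `fs`: 1 during task blocks, 0 during rest.
#' Durations that do not map to integer sample counts are rounded half up.
#'
#' @param protocol a [protocol_spec()]
#' @param fs sampling rate, Hz
#' @return a [channel_series()] of kind `"boxcar"`
#' @export
build_boxcar <- function(protocol, fs) {
  stopifnot(inherits(protocol, "protocol_spec"))
  n_lead <- seconds_to_samples(protocol$lead_in, fs)
  n_task <- seconds_to_samples(protocol$task_dur, fs)
  n_rest <- seconds_to_samples(protocol$rest_dur, fs)
  if (n_task < 1L || n_rest < 1L)
    stop("task_dur and rest_dur must span at least one sample at fs")
  block <- c(rep(1, n_task), rep(0, n_rest))
  channel_series(c(rep(0, n_lead), rep(block, protocol$n_blocks)),
                 fs = fs, kind = "boxcar")
}

#' Double-gamma hemodynamic response function specification
#'
#' Canonical double-gamma HRF: a positive gamma response minus a scaled
#' negative (undershoot) gamma. The two gamma shape parameters are solved
#' numerically at construction so the *difference* kernel attains its global
#' maximum exactly at `peak_time` and its global minimum exactly at
#' `undershoot_time` (the undershoot gamma's own mode is not at
#' `undershoot_time`: the positive response's decaying tail shifts the
#' difference's trough, and the solve compensates for that).
#'
#' @param peak_time time of response peak, seconds
#' @param undershoot_time time of undershoot trough, seconds
#' @param undershoot_ratio amplitude ratio undershoot/response (> 0)
#' @param kernel_duration kernel support, seconds (> undershoot_time)
#' @return an `hrf_spec` with the solved gamma shapes attached
#' @export
hrf_spec <- function(peak_time = 6, undershoot_time = 16,
                     undershoot_ratio = 1 / 6, kernel_duration = 32) {
  if (!(0 < peak_time && peak_time < undershoot_time &&
        undershoot_time < kernel_duration))
    stop("need 0 < peak_time < undershoot_time < kernel_duration")
  if (undershoot_ratio <= 0) stop("undershoot_ratio must be > 0")
  shapes <- solve_hrf_shapes(peak_time, undershoot_time, undershoot_ratio)
  structure(
    list(peak_time = peak_time, undershoot_time = undershoot_time,
         undershoot_ratio = undershoot_ratio,
         kernel_duration = kernel_duration,
         shape_response = shapes[1], shape_undershoot = shapes[2],
         rate = 1),
    class = "hrf_spec"
  )
}

# Solve the two gamma shapes (unit rate) so the difference kernel has
# stationary points at the requested peak and trough times.
solve_hrf_shapes <- function(p, u, ratio) {
  hprime <- function(t, a1, a2) {
    dgamma(t, a1, 1) * ((a1 - 1) / t - 1) -
      ratio * dgamma(t, a2, 1) * ((a2 - 1) / t - 1)
  }
  obj <- function(par) {
    a1 <- exp(par[1]); a2 <- exp(par[2])
    1e6 * (hprime(p, a1, a2)^2 + hprime(u, a1, a2)^2)
  }
  o <- stats::optim(log(c(p + 1, u + 1)), obj, method = "Nelder-Mead",
                    control = list(reltol = 1e-14, maxit = 5000))
  if (o$value > 1e-12)
    stop("could not solve HRF gamma shapes for the requested peak/undershoot")
  exp(o$par)
}

#' Sample the double-gamma HRF kernel
#'
#' Returns the kernel sampled on `t = 0, 1/fs, ..., kernel_duration`,
#' scaled to unit peak, with `kernel[1] = 0` at `t = 0`.
#'
#' @param hrf an [hrf_spec()]
#' @param fs sampling rate, Hz
#' @return numeric kernel vector
#' @export
sample_hrf <- function(hrf, fs) {
  stopifnot(inherits(hrf, "hrf_spec"))
  if (fs <= 0) stop("fs must be > 0")
  t <- seq(0, hrf$kernel_duration, by = 1 / fs)
  h <- dgamma(t, hrf$shape_response, hrf$rate) -
    hrf$undershoot_ratio * dgamma(t, hrf$shape_undershoot, hrf$rate)
  h / max(h)
}

#' Task-related component amplitudes (reference beta ground truth)
#'
#' The HbO2 amplitude is positive, the HbR amplitude negative at roughly
#' -1/3 of the HbO2 one. Values are in Molar internally; `uMol()` converts
#' from micromolar at the configuration boundary.
#'
#' @param hbo2_amp HbO2 component amplitude, Molar (> 0)
#' @param hbr_amp HbR component amplitude, Molar (< 0)
#' @param label preset label
#' @return an `amplitude_spec`
#' @export
amplitude_spec <- function(hbo2_amp, hbr_amp, label = "custom") {
  if (hbo2_amp <= 0) stop("hbo2_amp must be > 0")
  if (hbr_amp >= 0) stop("hbr_amp must be < 0")
  structure(list(hbo2_amp = hbo2_amp, hbr_amp = hbr_amp, label = label),
            class = "amplitude_spec")
}

#' Convert micromolar to Molar
#' @param x value in micromolar
#' @return value in Molar
#' @export
uMol <- function(x) x * 1e-6

#' The three task-amplitude presets
#'
#' Amplitude 1: 0.8 / -0.27 uMol, Amplitude 2: 0.5 / -0.17 uMol,
#' Amplitude 3: 0.3 / -0.1 uMol (HbO2 / HbR). These are the reference
#' beta values the filter sweep scores against.
#'
#' @return named list of three [amplitude_spec()] objects
#' @export
amplitude_presets <- function() {
  list(
    Amplitude1 = amplitude_spec(uMol(0.8), uMol(-0.27), "Amplitude1"),
    Amplitude2 = amplitude_spec(uMol(0.5), uMol(-0.17), "Amplitude2"),
    Amplitude3 = amplitude_spec(uMol(0.3), uMol(-0.1), "Amplitude3")
  )
}

# linear convolution, truncated to length of x (FFT-based via stats::convolve)
convolve_truncate <- function(x, kernel) {
  full <- stats::convolve(x, rev(kernel), type = "open")
  full[seq_along(x)]
}

#' Task-evoked component: boxcar convolved with the HRF
#'
#' Convolves the boxcar with the HRF kernel, truncates to the boxcar length,
#' rescales to unit peak magnitude, then multiplies by `amplitude`. Because
#' the same unit-peak shape is used as the GLM task regressor, the
#' generating amplitude is exactly the recoverable beta.
#'
#' @param boxcar a boxcar [channel_series()]
#' @param hrf_kernel sampled HRF kernel (same fs as the boxcar)
#' @param amplitude component amplitude (Molar; may be negative for HbR)
#' @return a [channel_series()] of kind `"regressor"` scaled by `amplitude`
#' @export
make_task_component <- function(boxcar, hrf_kernel, amplitude) {
  stopifnot(inherits(boxcar, "channel_series"))
  y <- convolve_truncate(boxcar$values, hrf_kernel)
  peak <- max(abs(y))
  if (peak > 0) y <- y / peak
  channel_series(y * amplitude, fs = boxcar$fs, kind = "regressor")
}
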