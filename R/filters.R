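#' Digital filter specification
#'
#' Describes one cell of the filter grid: band-pass (BP) or low-pass (LP)
#' characteristic; Butterworth (BW), windowed FIR, or moving-average
#' (MovAvg) family; order; cut-off frequencies. Cut-off conventions differ
#' by family and are documented in [design_filter()].
#'
#' @param characteristic `"BP"` or `"LP"`
#' @param family `"BW"`, `"FIR"` or `"MovAvg"`
#' @param order filter order (ignored for MovAvg, whose length is derived
#'   from `fc_high`)
#' @param fc_low lower cut-off, Hz (BP only)
#' @param fc_high upper (or only) cut-off, Hz
#' @param fs sampling rate, Hz
#' @return a `filter_spec`
#' @export
filter_spec <- function(characteristic = c("BP", "LP"),
                        family = c("BW", "FIR", "MovAvg"),
                        order = 3, fc_low = NULL, fc_high, fs = 5) {
  characteristic <- match.arg(characteristic)
  family <- match.arg(family)
  nyq <- fs / 2
  if (characteristic == "BP") {
    if (family == "MovAvg")
      stop("moving-average filters are low-pass only")
    if (is.null(fc_low) || !(0 < fc_low && fc_low < fc_high && fc_high < nyq))
      stop("BP needs 0 < fc_low < fc_high < fs/2")
  } else {
    if (!(0 < fc_high && fc_high < nyq))
      stop("LP needs 0 < fc_high < fs/2")
    fc_low <- NULL
  }
  if (family != "MovAvg" && order < 1) stop("order must be >= 1")
  structure(
    list(characteristic = characteristic, family = family,
         order = as.integer(order), fc_low = fc_low, fc_high = fc_high,
         fs = fs),
    class = "filter_spec"
  )
}

#' Short identifier for a filter spec
#' @param spec a [filter_spec()]
#' @return character id like `"BP_FIR_o1000_fc0.01-0.09"`
#' @export
spec_id <- function(spec) {
  fc <- if (is.null(spec$fc_low)) sprintf("fc%g", spec$fc_high) else
    sprintf("fc%g-%g", spec$fc_low, spec$fc_high)
  ord <- if (spec$family == "MovAvg") "" else sprintf("_o%d", spec$order)
  sprintf("%s_%s%s_%s", spec$characteristic, spec$family, ord, fc)
}

# moving-average window length whose first -3 dB point falls at fc_high
movavg_window <- function(fc_high, fs) max(2L, as.integer(round(0.443 * fs / fc_high)))

#' Design a filter from its specification
#'
#' * BW: Butterworth transfer-function coefficients via the bilinear
#'   transform (`signal::butter`); -3 dB at fc for a single pass.
#' * FIR: linear-phase Hamming-window design of length `order + 1`
#'   (`signal::fir1`); -6 dB at fc (the Matlab `fir1` convention).
#' * MovAvg: uniform window of length `round(0.443 * fs / fc_high)`, whose
#'   first -3 dB point falls at `fc_high`.
#'
#' @param spec a [filter_spec()]
#' @return a `filter_coeffs` with fields `b`, `a`, `group_delay` (samples,
#'   FIR/MovAvg), `spec`, `design_note`
#' @export
design_filter <- function(spec) {
  stopifnot(inherits(spec, "filter_spec"))
  nyq <- spec$fs / 2
  if (spec$family == "BW") {
    bf <- if (spec$characteristic == "BP")
      signal::butter(spec$order, c(spec$fc_low, spec$fc_high) / nyq,
                     type = "pass")
    else
      signal::butter(spec$order, spec$fc_high / nyq, type = "low")
    coeffs <- list(b = bf$b, a = bf$a, group_delay = NA_real_, spec = spec,
                   design_note = "Butterworth, bilinear transform, -3 dB at fc")
  } else if (spec$family == "FIR") {
    # scale = FALSE, then normalize with the Matlab fir1 convention:
    # exactly unit gain at DC for LP, at the passband centre for BP
    if (spec$characteristic == "BP") {
      b <- as.numeric(signal::fir1(spec$order,
                                   c(spec$fc_low, spec$fc_high) / nyq,
                                   type = "pass", scale = FALSE))
      w0 <- pi * (spec$fc_low + spec$fc_high) / 2 / nyq
      b <- b / Mod(polyval_z(b, exp(-1i * w0)))
    } else {
      b <- as.numeric(signal::fir1(spec$order, spec$fc_high / nyq,
                                   type = "low", scale = FALSE))
      b <- b / sum(b)
    }
    coeffs <- list(b = b, a = 1, group_delay = spec$order / 2,
                   spec = spec,
                   design_note = "linear-phase Hamming-window FIR, -6 dB at fc")
  } else {
    L <- movavg_window(spec$fc_high, spec$fs)
    coeffs <- list(b = rep(1 / L, L), a = 1, group_delay = (L - 1) / 2,
                   spec = spec,
                   design_note = sprintf(
                     "moving average, window %d samples (first -3 dB at fc)", L))
  }
  class(coeffs) <- "filter_coeffs"
  coeffs
}

# roots of a polynomial (coefficients in decreasing degree) via the
# eigenvalues of the companion matrix -- the algorithm behind Matlab's
# roots(); Jenkins-Traub (polyroot) gives different roundoff on
# near-unit-circle clusters, which matters for marginal stability calls
companion_roots <- function(p) {
  p <- p / p[1]
  n <- length(p) - 1L
  if (n < 1L) return(complex(0))
  A <- rbind(-p[-1], cbind(diag(n - 1L), rep(0, n - 1L)))
  eigen(A, only.values = TRUE)$values
}

#' z-plane stability of designed coefficients
#'
#' Pole magnitudes are the companion-matrix eigenvalues of the
#' transfer-function denominator exactly as designed, in double precision.
#' A filter is stable iff the largest pole magnitude is below
#' `1 - tol`. For high orders the realized denominator coefficients are
#' themselves rounded, so nominally stable designs can (and do) classify
#' unstable — that realization-level behaviour is the quantity of interest.
#'
#' @param coeffs a `filter_coeffs`
#' @param tol stability tolerance on the pole magnitude
#' @return a `stability_report` with `pole_magnitudes`, `is_stable`,
#'   `representation`
#' @export
check_stability <- function(coeffs, tol = 1e-12) {
  stopifnot(inherits(coeffs, "filter_coeffs"))
  a <- coeffs$a
  if (length(a) == 1L) {
    mags <- numeric(0)  # FIR / MovAvg: all poles at the origin
    stable <- TRUE
  } else if (any(!is.finite(a))) {
    # coefficient overflow at extreme orders: the realization is unusable
    mags <- Inf
    stable <- FALSE
  } else {
    mags <- Mod(companion_roots(a))
    stable <- max(mags) < 1 - tol
  }
  structure(list(pole_magnitudes = mags, is_stable = stable,
                 representation = "transfer-function"),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("<stability_report> %s  max|pole|=%s\n",
              if (x$is_stable) "stable" else "UNSTABLE",
              if (length(x$pole_magnitudes))
                format(max(x$pole_magnitudes), digits = 15) else "0 (FIR)"))
  invisible(x)
}

# one causal IIR pass started in the steady state of the first sample, so
# a constant record passes with exactly its steady-state gain
iir_pass_steady <- function(b, a, x) {
  y_ss <- x[1] * sum(b) / sum(a)
  as.numeric(signal::filter(b, a, x,
                            init.x = rep(x[1], max(length(b) - 1L, 0L)),
                            init.y = rep(y_ss, max(length(a) - 1L, 0L))))
}

# odd (anti-symmetric) reflection padding, as in Matlab's filtfilt
reflect_pad <- function(x, p) {
  n <- length(x)
  p <- min(p, n - 1L)
  left <- 2 * x[1] - x[(p + 1):2]
  right <- 2 * x[n] - x[(n - 1):(n - p)]
  list(x = c(left, x, right), p = p)
}

#' Apply a filter with zero net phase delay
#'
#' IIR filters are applied forward-backward (zero phase; magnitude response
#' squared). FIR and MovAvg filters are applied in a single pass and the
#' output advanced by the (rounded) group delay. Edges are handled by odd
#' reflection padding of three filter lengths (capped at the record
#' length); output length equals input length. Unstable IIR designs are
#' refused with the stability report attached to the error.
#'
#' @param coeffs a `filter_coeffs` from [design_filter()]
#' @param series a [channel_series()] (or numeric vector + `fs` ignored)
#' @return the filtered series
#' @export
apply_filter <- function(coeffs, series) {
  stopifnot(inherits(coeffs, "filter_coeffs"))
  is_iir <- length(coeffs$a) > 1L
  if (is_iir) {
    rep_ <- check_stability(coeffs)
    if (!rep_$is_stable) {
      e <- simpleError(sprintf(
        "unstable IIR filter (%s): max|pole| = %.6g; refusing to filter",
        spec_id(coeffs$spec), max(rep_$pole_magnitudes)))
      e$stability_report <- rep_
      stop(e)
    }
  }
  x <- as_series_values(series)
  n <- length(x)
  flen <- max(length(coeffs$b), length(coeffs$a))
  if (n <= flen)
    stop("series shorter than the filter; cannot handle edges")
  pad <- reflect_pad(x, 3L * flen)
  xp <- pad$x; p <- pad$p
  if (is_iir) {
    out <- iir_pass_steady(coeffs$b, coeffs$a, xp)
    out <- rev(iir_pass_steady(coeffs$b, coeffs$a, rev(out)))
    out <- out[(p + 1):(p + n)]
  } else {
    y <- as.numeric(signal::filter(coeffs$b, 1, xp))
    d <- as.integer(round(coeffs$group_delay))
    out <- y[(p + 1 + d):(p + n + d)]
  }
  if (inherits(series, "channel_series")) series_with_values(series, out) else out
}

#' Realized amplitude response on a frequency grid
#'
#' Evaluates the transfer function on `[0, fs/2]`. For IIR filters the
#' magnitude is squared, matching the forward-backward application in
#' [apply_filter()] (so the realized -6 dB point sits at the design's
#' -3 dB frequency).
#'
#' @param coeffs a `filter_coeffs`
#' @param n_points number of grid points (>= 64)
#' @return list with `freq` (Hz) and `magnitude` (linear gain)
#' @export
amplitude_response <- function(coeffs, n_points = 512) {
  stopifnot(inherits(coeffs, "filter_coeffs"))
  if (n_points < 64) stop("n_points must be >= 64")
  fs <- coeffs$spec$fs
  f <- seq(0, fs / 2, length.out = n_points)
  w <- 2 * pi * f / fs
  z <- exp(-1i * w)
  H <- polyval_z(coeffs$b, z) / polyval_z(coeffs$a, z)
  mag <- Mod(H)
  if (length(coeffs$a) > 1L) mag <- mag^2
  list(freq = f, magnitude = mag)
}

# evaluate sum(coef[k] * z^(k-1)) -- FIR/IIR polynomial in z^-1
polyval_z <- function(coef, z) {
  acc <- rep(0 + 0i, length(z))
  zp <- rep(1 + 0i, length(z))
  for (c in coef) {
    acc <- acc + c * zp
    zp <- zp * z
  }
  acc
}

#' Kaiser estimate of the FIR order for a transition band
#'
#' `N = (A - 7.95) / (2.285 * dw)` with `dw = 2*pi*transition_width/fs`,
#' rounded up to the next even integer. The order is inversely
#' proportional to the transition bandwidth.
#'
#' @param transition_width transition bandwidth, Hz, in `(0, fs/2)`
#' @param fs sampling rate, Hz
#' @param ripple_db stopband attenuation, dB (> 8)
#' @return even integer order estimate
#' @export
estimate_fir_order_kaiser <- function(transition_width, fs, ripple_db = 60) {
  if (!(transition_width > 0 && transition_width < fs / 2))
    stop("transition_width must be in (0, fs/2)")
  if (ripple_db <= 8) stop("ripple_db must exceed ~8 dB for the Kaiser formula")
  dw <- 2 * pi * transition_width / fs
  n <- (ripple_db - 7.95) / (2.285 * dw)
  as.integer(2 * ceiling(n / 2))
}

#' Welch power spectral density
#'
#' Averaged modified periodograms: Hamming-windowed segments of
#' `window_s` seconds with the given fractional overlap. One-sided density
#' normalization `2 |X|^2 / (fs * sum(w^2))` (DC and Nyquist bins not
#' doubled), so the integral of the PSD approximates the signal variance.
#'
#' @param series a [channel_series()] or numeric vector
#' @param fs sampling rate (taken from the series if not given)
#' @param window_s segment length, seconds
#' @param overlap fractional overlap in `[0, 1)`
#' @return list with `freq` (Hz) and `psd` (units^2 / Hz)
#' @export
welch_psd <- function(series, fs = NULL, window_s = 120, overlap = 0.5) {
  x <- as_series_values(series)
  if (is.null(fs)) {
    if (!inherits(series, "channel_series"))
      stop("fs required for plain numeric input")
    fs <- series$fs
  }
  n <- length(x)
  nseg <- seconds_to_samples(window_s, fs)
  if (nseg > n) {
    warning("window longer than series; using a single full-length segment")
    nseg <- n
  }
  step <- max(1L, as.integer(floor(nseg * (1 - overlap))))
  starts <- seq(1L, n - nseg + 1L, by = step)
  w <- hamming_window(nseg)
  U <- sum(w^2)
  nfreq <- nseg %/% 2L + 1L
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1L)] * w
    X <- stats::fft(seg)[seq_len(nfreq)]
    acc <- acc + Mod(X)^2
  }
  pxx <- acc / (length(starts) * fs * U)
  # one-sided: double interior bins
  dbl <- rep(2, nfreq); dbl[1] <- 1
  if (nseg %% 2L == 0L) dbl[nfreq] <- 1
  list(freq = (seq_len(nfreq) - 1L) * fs / nseg, psd = pxx * dbl)
}

hamming_window <- function(n) {
  if (n == 1L) return(1)
  0.54 - 0.46 * cos(2 * pi * (0:(n - 1)) / (n - 1))
}

#' The study's default filter grid
#'
#' All combinations evaluated by the sweep: BP (BW, FIR) x orders
#' {3, 4, 5, 20, 100, 200, 500, 1000} x pass bands {[0.01, 0.09],
#' [0.01, 0.2], [0.01, 0.3], [0.01, 0.5]} Hz, and LP (BW, FIR, same orders;
#' plus MovAvg, no order) x cut-offs {0.09, 0.1, 0.14, 0.5} Hz.
#'
#' @param fs sampling rate, Hz
#' @param orders filter orders for BW and FIR
#' @param bp_high upper edges of the BP bands (lower edge fixed at 0.01 Hz)
#' @param lp_fc LP cut-offs
#' @param families families to include
#' @return list of [filter_spec()] objects
#' @export
default_filter_grid <- function(fs = 5,
                                orders = c(3, 4, 5, 20, 100, 200, 500, 1000),
                                bp_high = c(0.09, 0.2, 0.3, 0.5),
                                lp_fc = c(0.09, 0.1, 0.14, 0.5),
                                families = c("BW", "FIR", "MovAvg")) {
  grid <- list()
  for (fam in setdiff(families, "MovAvg")) {
    for (ord in orders) {
      for (hi in bp_high)
        grid[[length(grid) + 1L]] <-
          filter_spec("BP", fam, ord, fc_low = 0.01, fc_high = hi, fs = fs)
      for (fc in lp_fc)
        grid[[length(grid) + 1L]] <-
          filter_spec("LP", fam, ord, fc_high = fc, fs = fs)
    }
  }
  if ("MovAvg" %in% families)
    for (fc in lp_fc)
      grid[[length(grid) + 1L]] <-
        filter_spec("LP", "MovAvg", fc_high = fc, fs = fs)
  names(grid) <- vapply(grid, spec_id, character(1))
  grid
}
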