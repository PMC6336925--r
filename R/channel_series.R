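#' Sampled fNIRS channel time series
#'
#' Light-weight container for a uniformly sampled single-channel signal.
#' `kind` records what the samples are: raw light intensity, optical-density
#' change (dOD), or chromophore concentration change (HbO2 / HbR, in Molar).
#' `wavelength` (nm) is meaningful only for intensity / OD series.
#'
#' @param values numeric vector of samples, no missing values, length >= 2
#' @param fs sampling rate in Hz
#' @param kind one of `"intensity"`, `"OD"`, `"HbO2"`, `"HbR"`, or
#'   `"boxcar"` / `"regressor"` for unit-less design signals
#' @param wavelength optional wavelength in nm (intensity / OD only)
#' @return an object of class `channel_series`
#' @export
channel_series <- function(values, fs,
                           kind = c("HbO2", "HbR", "OD", "intensity",
                                    "boxcar", "regressor"),
                           wavelength = NULL) {
  kind <- match.arg(kind)
  values <- as.numeric(values)
  if (length(values) < 2L)
    stop("channel_series needs at least 2 samples")
  if (anyNA(values) || any(!is.finite(values)))
    stop("channel_series values must be finite and non-missing")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("fs must be a single positive number (Hz)")
  structure(
    list(values = values, fs = fs, kind = kind, wavelength = wavelength),
    class = "channel_series"
  )
}

#' @export
print.channel_series <- function(x, ...) {
  dur <- length(x$values) / x$fs
  cat(sprintf("<channel_series> kind=%s  n=%d  fs=%g Hz  duration=%g s\n",
              x$kind, length(x$values), x$fs, dur))
  invisible(x)
}

#' @export
length.channel_series <- function(x) length(x$values)

#' Time axis of a channel series
#'
#' @param x a `channel_series`
#' @return numeric vector of sample times in seconds, starting at 0
#' @export
series_time <- function(x) {
  stopifnot(inherits(x, "channel_series"))
  (seq_along(x$values) - 1L) / x$fs
}

# replace the samples of a series, keeping metadata
series_with_values <- function(x, values) {
  x$values <- as.numeric(values)
  x
}

as_series_values <- function(x) {
  if (inherits(x, "channel_series")) x$values else as.numeric(x)
}
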