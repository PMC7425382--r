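#' Uniformly sampled single-channel time series
#'
#' Lightweight container for a region-of-interest (ROI) source time course.
#' Units are arbitrary (noise-normalized source estimates carry no absolute
#' scale); all amplitude-bearing outputs of the package are therefore
#' unit-relative.
#'
#' @param samples Numeric vector of samples; must be finite, length >= 2.
#' @param fs Sampling frequency in Hz (> 0).
#' @param t0 Time of the first sample in seconds.
#' @return An object of class `time_series` with fields `samples`, `fs`, `t0`.
#' @export
time_series <- function(samples, fs, t0 = 0) {
  samples <- as.numeric(samples)
  if (length(samples) < 2) stop("time_series needs at least 2 samples")
  if (!all(is.finite(samples))) stop("time_series samples must be finite")
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) stop("fs must be a positive scalar")
  structure(list(samples = samples, fs = fs, t0 = t0), class = "time_series")
}

#' @export
print.time_series <- function(x, ...) {
  cat(sprintf("<time_series> %d samples @ %g Hz (%.1f s), t0 = %g s\n",
              length(x$samples), x$fs, length(x$samples) / x$fs, x$t0))
  invisible(x)
}

#' @export
length.time_series <- function(x) length(x$samples)

#' Duration of a time series in seconds
#' @param ts A `time_series`.
#' @return Duration in seconds.
#' @export
ts_duration <- function(ts) length(ts$samples) / ts$fs

#' Amplitude envelope of a band-limited series
#'
#' Container for the magnitude of the analytic signal ("instantaneous beta
#' power" when the band is 13-30 Hz).
#'
#' @param magnitude Non-negative numeric vector.
#' @param fs Sampling frequency in Hz.
#' @param band Length-2 numeric, the (low, high) band edges in Hz.
#' @param t0 Time of the first retained sample in seconds.
#' @return An object of class `envelope`.
#' @export
envelope <- function(magnitude, fs, band, t0 = 0) {
  magnitude <- as.numeric(magnitude)
  if (any(magnitude < 0)) stop("envelope magnitude must be non-negative")
  if (fs <= 0) stop("fs must be positive")
  structure(list(magnitude = magnitude, fs = fs, band = band, t0 = t0),
            class = "envelope")
}

#' @export
print.envelope <- function(x, ...) {
  cat(sprintf("<envelope> %d samples @ %g Hz, band %g-%g Hz, median %.3g\n",
              length(x$magnitude), x$fs, x$band[1], x$band[2],
              stats::median(x$magnitude)))
  invisible(x)
}
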