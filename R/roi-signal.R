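#' Combine source time courses within an ROI into one time course
#'
#' Reduces an n_sources x n_samples matrix to a single representative time
#' course: the first right-singular vector of the SVD of the source matrix,
#' scaled by its singular value. The overall sign is normalized against the
#' source orientations: the mean of (first left-singular vector x orientation
#' sign) is made non-negative, so flipping every source and its orientation
#' leaves the output unchanged.
#'
#' @param source_tcs Numeric matrix, rows = sources, columns = samples.
#' @param orientations Numeric vector of per-source orientation signs
#'   (only the sign is used); defaults to all +1.
#' @param fs Sampling frequency in Hz of the resulting series.
#' @param t0 Time of the first sample in seconds.
#' @return A [time_series].
#' @export
combine_roi <- function(source_tcs, orientations = NULL, fs = 1000, t0 = 0) {
  source_tcs <- as.matrix(source_tcs)
  if (nrow(source_tcs) < 1) stop("need at least one source")
  if (all(source_tcs == 0)) stop("all-zero source matrix has no principal component")
  if (is.null(orientations)) orientations <- rep(1, nrow(source_tcs))
  if (length(orientations) != nrow(source_tcs))
    stop("orientations must have one entry per source")
  sv <- svd(source_tcs, nu = 1, nv = 1)
  tc <- sv$v[, 1] * sv$d[1]
  if (mean(sv$u[, 1] * sign(orientations)) < 0) tc <- -tc
  time_series(tc, fs = fs, t0 = t0)
}

#' Design the beta band-pass FIR filter
#'
#' Linear-phase band-pass built as the difference of two Hamming-windowed
#' sinc low-pass filters, so that the two pass-band edges can have different
#' transition bandwidths. Each low-pass cutoff sits half a transition width
#' outside its pass-band edge and its length follows the Hamming rule
#' (transition width ~ 3.3 / N cycles/sample), giving ~53 dB stop-band
#' attenuation.
#'
#' @param fs Sampling frequency, Hz.
#' @param low,high Pass-band edges, Hz.
#' @param trans_low,trans_high Transition bandwidths at the lower/upper
#'   edges, Hz.
#' @return Numeric vector of filter taps (odd length, symmetric).
#' @export
design_bandpass_fir <- function(fs, low = 13, high = 30,
                                trans_low = 3.25, trans_high = 7.5) {
  if (fs <= 2 * high) stop("sampling rate too low for the requested band")
  if (low <= trans_low / 2) stop("lower transition band extends below 0 Hz")
  lp <- function(cutoff_hz, trans_hz) {
    ntaps <- ceiling(3.3 * fs / trans_hz)
    if (ntaps %% 2 == 0) ntaps <- ntaps + 1
    m <- (ntaps - 1) / 2
    k <- -m:m
    fc <- cutoff_hz / (fs / 2)
    h <- ifelse(k == 0, fc, sin(pi * fc * k) / (pi * k))
    h * (0.54 + 0.46 * cos(pi * k / m))
  }
  h_hi <- lp(high + trans_high / 2, trans_high)
  h_lo <- lp(low - trans_low / 2, trans_low)
  n <- max(length(h_hi), length(h_lo))
  pad <- function(h) {
    d <- (n - length(h)) / 2
    c(rep(0, d), h, rep(0, d))
  }
  pad(h_hi) - pad(h_lo)
}

#' Frequency response magnitude of an FIR filter
#'
#' @param h Filter taps.
#' @param freqs_hz Frequencies at which to evaluate, Hz.
#' @param fs Sampling frequency, Hz.
#' @return Numeric vector of gain magnitudes.
#' @export
fir_gain <- function(h, freqs_hz, fs) {
  vapply(freqs_hz, function(f) {
    Mod(sum(h * exp(-2i * pi * f / fs * seq_along(h))))
  }, numeric(1))
}

## FFT convolution with exact group-delay compensation; h must be odd-length
## symmetric (linear phase), so the one-pass output is zero phase.
.filter_zero_phase <- function(x, h) {
  n <- length(x)
  m <- (length(h) - 1) / 2
  nfft <- stats::nextn(n + length(h) - 1, 2)
  y <- Re(stats::fft(stats::fft(c(x, rep(0, nfft - n))) *
                     stats::fft(c(h, rep(0, nfft - length(h)))), inverse = TRUE)) / nfft
  y[(m + 1):(m + n)]
}

#' Beta band-pass filter a time series
#'
#' Zero-phase FIR band-pass (default 13-30 Hz). The filter is linear phase
#' and applied in a single pass with the group delay compensated exactly, so
#' the output is zero phase and the same length as the input; the first and
#' last half-filter lengths contain edge transients (see
#' [hilbert_envelope()]'s trim).
#'
#' @param ts A [time_series].
#' @param low,high Pass-band edges, Hz.
#' @param trans_low,trans_high Transition bandwidths, Hz.
#' @return A [time_series] of the same length.
#' @export
bandpass_beta <- function(ts, low = 13, high = 30,
                          trans_low = 3.25, trans_high = 7.5) {
  stopifnot(inherits(ts, "time_series"))
  h <- design_bandpass_fir(ts$fs, low, high, trans_low, trans_high)
  if (length(ts$samples) <= length(h))
    stop("record shorter than the filter; use a longer record or wider transitions")
  out <- time_series(.filter_zero_phase(ts$samples, h), fs = ts$fs, t0 = ts$t0)
  attr(out, "band") <- c(low, high)
  out
}

## analytic signal via FFT (positive-frequency doubling)
.analytic <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  mult <- rep(0, n)
  mult[1] <- 1
  if (n %% 2 == 0) {
    mult[n / 2 + 1] <- 1
    mult[2:(n / 2)] <- 2
  } else {
    mult[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * mult, inverse = TRUE) / n
}

#' Hilbert amplitude envelope
#'
#' Magnitude of the analytic signal of a band-limited series — the
#' instantaneous band amplitude. The first and last `edge_trim_s` seconds are
#' discarded to remove filter and Hilbert edge transients before any burst or
#' threshold computation.
#'
#' @param ts A band-limited [time_series] (contract, not enforced).
#' @param edge_trim_s Seconds trimmed from each end (default 1).
#' @return An [envelope]; `t0` is advanced by the trim.
#' @export
hilbert_envelope <- function(ts, edge_trim_s = 1) {
  stopifnot(inherits(ts, "time_series"))
  n <- length(ts$samples)
  trim <- round(edge_trim_s * ts$fs)
  if (2 * trim >= n) stop("edge_trim_s must be less than half the record")
  mag <- Mod(.analytic(ts$samples))
  keep <- if (trim > 0) mag[(trim + 1):(n - trim)] else mag
  band <- attr(ts, "band")
  if (is.null(band)) band <- c(NA_real_, NA_real_)
  envelope(keep, fs = ts$fs, band = band, t0 = ts$t0 + trim / ts$fs)
}
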