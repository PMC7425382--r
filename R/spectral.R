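#' Welch power spectral density
#'
#' Average of Hann-tapered periodograms over consecutive overlapping
#' segments (default 3 s with 50% overlap), restricted to `[fmin, fmax]`.
#' One-sided density scaling (power / Hz), so band-limited variance is the
#' integral of the PSD over the band.
#'
#' @param ts A [time_series].
#' @param seg_len_s Segment length in seconds.
#' @param overlap Fractional overlap between consecutive segments.
#' @param fmin,fmax Frequency range retained, Hz.
#' @return A list of class `psd`: `freqs` (Hz, ascending), `power`
#'   (non-negative), `n_segments`.
#' @export
welch_psd <- function(ts, seg_len_s = 3.0, overlap = 0.5, fmin = 1, fmax = 48) {
  stopifnot(inherits(ts, "time_series"))
  x <- ts$samples
  fs <- ts$fs
  nper <- round(seg_len_s * fs)
  if (length(x) < nper) stop("record shorter than one segment")
  step <- max(1, round(nper * (1 - overlap)))
  starts <- seq(1, length(x) - nper + 1, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, nper - 1) / (nper - 1))   # Hann
  u <- sum(w^2)
  acc <- numeric(nper)
  for (s0 in starts) {
    seg <- x[s0:(s0 + nper - 1)]
    seg <- (seg - mean(seg)) * w
    acc <- acc + Mod(stats::fft(seg))^2
  }
  pxx <- acc / length(starts) / (fs * u)
  nf <- floor(nper / 2)
  freqs <- (0:nf) * fs / nper
  pxx <- pxx[1:(nf + 1)]
  pxx[2:(nf + 1)] <- 2 * pxx[2:(nf + 1)]
  if (nper %% 2 == 0) pxx[nf + 1] <- pxx[nf + 1] / 2
  keep <- freqs >= fmin & freqs <= fmax
  structure(list(freqs = freqs[keep], power = pxx[keep],
                 n_segments = length(starts)), class = "psd")
}

#' @export
print.psd <- function(x, ...) {
  cat(sprintf("<psd> %d bins, %.2f-%.2f Hz, %d segments\n",
              length(x$freqs), min(x$freqs), max(x$freqs), x$n_segments))
  invisible(x)
}

#' Relative band power
#'
#' Trapezoidal integral of the PSD over the band divided by the integral
#' over the full retained spectrum; invariant to global PSD scaling.
#'
#' @param psd A `psd`.
#' @param band Length-2 numeric (low, high), Hz; must lie within the PSD's
#'   frequency range.
#' @return Fraction in `[0, 1]`.
#' @export
relative_band_power <- function(psd, band = c(13, 30)) {
  stopifnot(inherits(psd, "psd"))
  if (band[1] >= band[2]) stop("empty band")
  if (band[1] < min(psd$freqs) || band[2] > max(psd$freqs))
    stop("band outside the PSD frequency range")
  trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  ## interpolate the band edges onto the grid so the ratio is exact
  in_band <- psd$freqs >= band[1] & psd$freqs <= band[2]
  fx <- psd$freqs[in_band]
  fy <- psd$power[in_band]
  edge <- stats::approx(psd$freqs, psd$power, xout = band)$y
  fx <- c(band[1], fx, band[2])
  fy <- c(edge[1], fy, edge[2])
  dup <- duplicated(fx)
  trapz(fx[!dup], fy[!dup]) / trapz(psd$freqs, psd$power)
}

## single Gaussian in log10 power over linear frequency
.gauss <- function(f, center, height, width) height * exp(-(f - center)^2 / (2 * width^2))

## fit one Gaussian to the residual around its largest peak
.fit_peak <- function(freqs, resid, min_width = 1, max_width = 12) {
  i0 <- which.max(resid)
  c0 <- freqs[i0]
  h0 <- resid[i0]
  ## initial width: half-height extent around the peak
  above <- resid >= h0 / 2
  run <- range(which(above & cumsum(!above) == cumsum(!above)[i0]))
  w0 <- max((freqs[run[2]] - freqs[run[1]]) / 2.355, min_width)
  obj <- function(p) {
    g <- .gauss(freqs, p[1], p[2], p[3])
    sum((resid - g)^2)
  }
  fit <- try(stats::optim(c(c0, h0, w0), obj, method = "L-BFGS-B",
                          lower = c(min(freqs), 0, min_width),
                          upper = c(max(freqs), 2 * max(h0, 1e-6), max_width)),
             silent = TRUE)
  if (inherits(fit, "try-error")) return(NULL)
  list(center = fit$par[1], height = fit$par[2], width = fit$par[3])
}

## aperiodic line in log-log space: log10 P = intercept - exponent * log10 f
.fit_aperiodic_line <- function(logf, logp, robust = TRUE) {
  fit <- stats::lm.fit(cbind(1, logf), logp)
  if (robust) {
    res <- logp - cbind(1, logf) %*% fit$coefficients
    keep <- res <= stats::quantile(res, 0.75)   # drop top-quartile positive residuals
    fit <- stats::lm.fit(cbind(1, logf[keep]), logp[keep])
  }
  c(intercept = fit$coefficients[1], slope = fit$coefficients[2])
}

#' Parameterize a PSD into aperiodic 1/f and Gaussian peaks
#'
#' Iterative decomposition of the log10 spectrum: (1) robust log-log linear
#' fit of the aperiodic component (OLS, refit excluding the top-quartile
#' positive residuals so narrow-band peaks do not bias the line);
#' (2) subtract; (3) repeatedly fit a Gaussian (log10-power height over
#' linear frequency) to the largest remaining residual peak exceeding the
#' detection criterion (2 SD of the flattened residual), subtract, stopping
#' at `max_peaks`; (4) refit the aperiodic line to the peak-subtracted
#' spectrum; (5) report the combined model's R^2. The aperiodic exponent is
#' stored positive for a 1/f-type spectrum (model
#' `log10 P = intercept - exponent * log10 f`, intercept at 1 Hz).
#'
#' @param psd A `psd` with strictly positive power.
#' @param max_peaks Maximum number of Gaussian peaks (default 8).
#' @param peak_threshold_sd Detection criterion in SDs of the flattened
#'   residual (default 2).
#' @param min_peak_height Absolute floor on a detectable peak, log10-power
#'   units (default 0.01, ~2% power), so numerically flat residuals yield
#'   no peaks.
#' @param min_width,max_width Gaussian width bounds, Hz.
#' @param beta_band Band searched for the beta peak, Hz.
#' @return A list of class `spectral_fit`: `intercept`, `exponent`, `peaks`
#'   (data frame center_hz/height_log10/width_hz), `r2`, `relative_beta`,
#'   `beta_peak_freq`, `beta_peak_power` (NA when no beta peak is found).
#' @export
fit_aperiodic_periodic <- function(psd, max_peaks = 8, peak_threshold_sd = 2,
                                   min_peak_height = 0.01,
                                   min_width = 1, max_width = 12,
                                   beta_band = c(13, 30)) {
  stopifnot(inherits(psd, "psd"))
  if (any(psd$power <= 0)) stop("all PSD power values must be positive")
  logf <- log10(psd$freqs)
  logp <- log10(psd$power)
  line <- .fit_aperiodic_line(logf, logp)
  resid <- logp - (line[1] + line[2] * logf)
  peaks <- list()
  for (i in seq_len(max_peaks)) {
    thr <- max(peak_threshold_sd * stats::sd(resid), min_peak_height)
    if (max(resid) < thr) break
    pk <- .fit_peak(psd$freqs, resid, min_width, max_width)
    if (is.null(pk) || pk$height <= 0) break
    peaks[[length(peaks) + 1]] <- pk
    resid <- resid - .gauss(psd$freqs, pk$center, pk$height, pk$width)
  }
  peak_sum <- if (length(peaks)) {
    Reduce(`+`, lapply(peaks, function(p) .gauss(psd$freqs, p$center, p$height, p$width)))
  } else rep(0, length(psd$freqs))
  line2 <- .fit_aperiodic_line(logf, logp - peak_sum, robust = FALSE)
  model <- line2[1] + line2[2] * logf + peak_sum
  r2 <- 1 - sum((logp - model)^2) / sum((logp - mean(logp))^2)
  peak_df <- if (length(peaks)) {
    data.frame(center_hz = vapply(peaks, `[[`, 0, "center"),
               height_log10 = vapply(peaks, `[[`, 0, "height"),
               width_hz = vapply(peaks, `[[`, 0, "width"))
  } else {
    data.frame(center_hz = numeric(0), height_log10 = numeric(0),
               width_hz = numeric(0))
  }
  in_beta <- peak_df$center_hz >= beta_band[1] & peak_df$center_hz <= beta_band[2]
  if (any(in_beta)) {
    bp <- peak_df[in_beta, ][which.max(peak_df$height_log10[in_beta]), ]
    beta_freq <- bp$center_hz
    beta_pow <- bp$height_log10
  } else {
    beta_freq <- NA_real_
    beta_pow <- NA_real_
  }
  structure(list(intercept = unname(line2[1]), exponent = unname(-line2[2]),
                 peaks = peak_df, r2 = r2,
                 relative_beta = relative_band_power(psd, beta_band),
                 beta_peak_freq = beta_freq, beta_peak_power = beta_pow),
            class = "spectral_fit")
}

#' @export
print.spectral_fit <- function(x, ...) {
  cat(sprintf("<spectral_fit> exponent %.3f, intercept %.3f, %d peak(s), R2 %.3f\n",
              x$exponent, x$intercept, nrow(x$peaks), x$r2))
  if (!is.na(x$beta_peak_freq))
    cat(sprintf("  beta peak: %.1f Hz, height %.3f; relative beta %.3f\n",
                x$beta_peak_freq, x$beta_peak_power, x$relative_beta))
  invisible(x)
}

#' Spectral features for every record of a cohort
#'
#' Welch PSD + aperiodic/periodic fit per record, returned as a tidy table.
#'
#' @param cohort A `cohort` or list of records with `signal`.
#' @param config Pipeline configuration list.
#' @return Data frame: subject, group, session, relative_beta, intercept,
#'   exponent, beta_peak_freq, beta_peak_power, r2, n_peaks.
#' @export
spectral_cohort <- function(cohort, config = default_config()) {
  records <- if (inherits(cohort, "cohort")) cohort$records else cohort
  rows <- lapply(records, function(rec) {
    p <- welch_psd(rec$signal, seg_len_s = config$psd$seg_len_s,
                   overlap = config$psd$overlap,
                   fmin = config$psd$fmin, fmax = config$psd$fmax)
    fit <- fit_aperiodic_periodic(p, max_peaks = config$fit$max_peaks)
    data.frame(subject = rec$subject_id, group = rec$group,
               session = rec$session,
               relative_beta = fit$relative_beta,
               intercept = fit$intercept, exponent = fit$exponent,
               beta_peak_freq = fit$beta_peak_freq,
               beta_peak_power = fit$beta_peak_power,
               r2 = fit$r2, n_peaks = nrow(fit$peaks))
  })
  do.call(rbind, rows)
}
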