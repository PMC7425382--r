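## center statistic for the threshold reference
.env_center <- function(mag, center = c("median", "mean", "mode")) {
  center <- match.arg(center)
  switch(center,
         median = stats::median(mag),
         mean = mean(mag),
         mode = {
           d <- stats::density(mag, n = 512)
           d$x[which.max(d$y)]
         })
}

#' Detect suprathreshold burst events in an envelope
#'
#' The threshold is expressed in multiples of the envelope median (the
#' record's own dynamic range): `T = k * median(magnitude)` by default, or
#' `T = (1 + k) * median` with `mode = "additive"`. Every envelope local
#' maximum above the threshold is a candidate event; its onset and offset
#' are found by walking outward from the peak to the first samples below
#' half the peak amplitude, with linear interpolation to sub-sample
#' crossing times. Events whose half-max window is truncated by the record
#' edge are discarded; candidates with overlapping half-max windows are
#' merged keeping the larger peak (greedy, in descending peak order), so
#' returned events are disjoint and the event count is non-increasing in k.
#'
#' @param env An [envelope].
#' @param k Threshold multiplier (>= 1, i.e. at or above the median).
#' @param center Center statistic the threshold multiplies
#'   (`"median"` default; `"mean"`, `"mode"` available).
#' @param mode `"multiplicative"` (T = k * center, default) or `"additive"`
#'   (T = center + k * center).
#' @return Data frame of class `burst_events`: onset_s, offset_s,
#'   peak_time_s, peak_amp, duration_s; times in the envelope's clock
#'   (i.e. including `t0`).
#' @export
detect_events <- function(env, k, center = "median",
                          mode = c("multiplicative", "additive")) {
  stopifnot(inherits(env, "envelope"))
  mode <- match.arg(mode)
  if (!length(env$magnitude)) stop("empty envelope")
  if (k < 1) stop("threshold multiplier k must be >= 1")
  mag <- env$magnitude
  ctr <- .env_center(mag, center)
  thr <- if (mode == "multiplicative") k * ctr else ctr + k * ctr
  empty <- data.frame(onset_s = numeric(0), offset_s = numeric(0),
                      peak_time_s = numeric(0), peak_amp = numeric(0),
                      duration_s = numeric(0))
  class(empty) <- c("burst_events", "data.frame")
  n <- length(mag)
  ## candidate events: every local maximum above threshold (plateaus count
  ## once, at their first sample)
  cand <- which(mag > thr &
                  mag >= c(-Inf, mag[-n]) &
                  mag > c(mag[-1], -Inf))
  if (!length(cand)) return(empty)
  onset <- offset <- ptime <- pamp <- rep(NA_real_, length(cand))
  for (i in seq_along(cand)) {
    p <- cand[i]
    half <- mag[p] / 2
    l <- p
    while (l > 1L && mag[l] >= half) l <- l - 1L
    if (mag[l] >= half) next                       # truncated at left edge
    lt <- l + (half - mag[l]) / (mag[l + 1L] - mag[l])
    u <- p
    while (u < n && mag[u] >= half) u <- u + 1L
    if (mag[u] >= half) next                       # truncated at right edge
    rt <- (u - 1L) + (mag[u - 1L] - half) / (mag[u - 1L] - mag[u])
    onset[i] <- lt; offset[i] <- rt; ptime[i] <- p; pamp[i] <- mag[p]
  }
  ok <- !is.na(onset)
  ev <- data.frame(onset = onset[ok], offset = offset[ok],
                   ptime = ptime[ok], pamp = pamp[ok])
  if (!nrow(ev)) return(empty)
  if (nrow(ev) > 1) {
    ## merge in descending peak order: an event survives unless its
    ## half-max window overlaps that of an already-accepted larger peak;
    ## survival therefore depends only on larger candidates, which makes
    ## the count non-increasing in k. Overlap is local, so the greedy runs
    ## within clusters of transitively overlapping windows.
    ev <- ev[order(ev$onset), ]
    cluster <- cumsum(c(1, ev$onset[-1] > cummax(ev$offset)[-nrow(ev)]))
    keep_all <- logical(nrow(ev))
    for (cl in split(seq_len(nrow(ev)), cluster)) {
      if (length(cl) == 1) { keep_all[cl] <- TRUE; next }
      o <- cl[order(-ev$pamp[cl], ev$onset[cl])]
      acc_on <- numeric(0)
      acc_off <- numeric(0)
      for (i in o) {
        if (!any(ev$onset[i] <= acc_off & ev$offset[i] >= acc_on)) {
          keep_all[i] <- TRUE
          acc_on <- c(acc_on, ev$onset[i])
          acc_off <- c(acc_off, ev$offset[i])
        }
      }
    }
    ev <- ev[keep_all, ]
  }
  ## sample index 1 corresponds to time t0; index i -> t0 + (i-1)/fs
  out <- data.frame(
    onset_s = env$t0 + (ev$onset - 1) / env$fs,
    offset_s = env$t0 + (ev$offset - 1) / env$fs,
    peak_time_s = env$t0 + (ev$ptime - 1) / env$fs,
    peak_amp = ev$pamp)
  out$duration_s <- out$offset_s - out$onset_s
  rownames(out) <- NULL
  class(out) <- c("burst_events", "data.frame")
  out
}

#' Data-driven threshold selection across subjects
#'
#' For each candidate multiplier k and each subject: partition the envelope
#' into consecutive non-overlapping segments (default 3.0 s, remainder
#' dropped), compute per-segment mean envelope amplitude and the count of
#' events whose peak time falls in the segment, and take the Pearson
#' correlation across segments. Per-k correlations are averaged across
#' subjects (subjects with zero count variance at a given k are excluded
#' from that k's average, with a warning) and the multiplier with the
#' highest mean correlation is selected (first maximum on ties).
#'
#' @param envelopes List of [envelope]s, one per subject record.
#' @param k_grid Ascending numeric vector of candidate multipliers
#'   (default 1 to 5 in steps of 0.1).
#' @param segment_len_s Segment length in seconds (default 3).
#' @param center,mode Passed to [detect_events()].
#' @return A list of class `threshold_grid`: `k_values`, `mean_r`,
#'   `k_star`, `r_matrix` (subjects x k), `segment_len_s`.
#' @export
optimize_threshold <- function(envelopes, k_grid = seq(1, 5, by = 0.1),
                               segment_len_s = 3.0, center = "median",
                               mode = "multiplicative") {
  if (length(envelopes) < 2) stop("need envelopes from at least 2 subjects")
  if (is.unsorted(k_grid, strictly = TRUE)) stop("k_grid must be strictly ascending")
  nsub <- length(envelopes)
  rmat <- matrix(NA_real_, nsub, length(k_grid))
  n_excluded <- 0L
  for (s in seq_len(nsub)) {
    env <- envelopes[[s]]
    seg_n <- round(segment_len_s * env$fs)
    nseg <- length(env$magnitude) %/% seg_n
    if (nseg < 2) stop("each envelope must contain at least 2 full segments")
    segid <- rep(seq_len(nseg), each = seg_n)
    seg_amp <- tapply(env$magnitude[seq_len(nseg * seg_n)], segid, mean)
    for (ki in seq_along(k_grid)) {
      ev <- detect_events(env, k_grid[ki], center = center, mode = mode)
      ## segment of an event = segment containing its peak time
      pk_idx <- round((ev$peak_time_s - env$t0) * env$fs) + 1
      seg_of <- (pk_idx - 1) %/% seg_n + 1
      seg_of <- seg_of[seg_of >= 1 & seg_of <= nseg]
      cnt <- tabulate(seg_of, nbins = nseg)
      if (stats::sd(cnt) == 0) { n_excluded <- n_excluded + 1L; next }
      rmat[s, ki] <- stats::cor(seg_amp, cnt)
    }
  }
  if (n_excluded > 0)
    warning(sprintf("%d subject/threshold cells had zero count variance and were excluded", n_excluded))
  mean_r <- colMeans(rmat, na.rm = TRUE)
  mean_r[is.nan(mean_r)] <- NA_real_
  if (all(is.na(mean_r))) stop("no threshold produced a defined correlation")
  k_star <- k_grid[which.max(mean_r)]
  structure(list(k_values = k_grid, mean_r = mean_r, k_star = k_star,
                 r_matrix = rmat, segment_len_s = segment_len_s),
            class = "threshold_grid")
}

#' @export
print.threshold_grid <- function(x, ...) {
  cat(sprintf("<threshold_grid> k in [%g, %g] (%d values), k* = %g (mean r = %.3f)\n",
              min(x$k_values), max(x$k_values), length(x$k_values), x$k_star,
              max(x$mean_r, na.rm = TRUE)))
  invisible(x)
}

#' Summarize burst features for one subject record
#'
#' The four burst features: rate of occurrence (bursts per analyzed minute),
#' per-event half-max duration, inter-burst interval (offset of one burst to
#' onset of the next; same half-max boundaries as the duration), and peak
#' amplitude — plus their medians.
#'
#' @param events A `burst_events` data frame (sorted by onset).
#' @param env The [envelope] the events came from (for analyzed duration).
#' @param subject,group,session Record metadata.
#' @return A list of class `subject_burst_summary`; `as.data.frame` gives a
#'   one-row summary table.
#' @export
summarize_subject <- function(events, env, subject = NA_character_,
                              group = NA_character_, session = NA_integer_) {
  minutes <- length(env$magnitude) / env$fs / 60
  n <- nrow(events)
  durs <- events$duration_s * 1000
  amps <- events$peak_amp
  ibis <- if (n >= 2) (events$onset_s[-1] - events$offset_s[-n]) * 1000 else numeric(0)
  structure(list(subject = subject, group = group, session = session,
                 n_bursts = n, analyzed_min = minutes,
                 rate_per_min = n / minutes,
                 durations_ms = durs, ibis_ms = ibis, peak_amps = amps,
                 median_duration_ms = stats::median(durs),
                 median_ibi_ms = stats::median(ibis),
                 median_peak_amp = stats::median(amps)),
            class = "subject_burst_summary")
}

#' @export
as.data.frame.subject_burst_summary <- function(x, ...) {
  data.frame(subject = x$subject, group = x$group, session = x$session,
             n_bursts = x$n_bursts, analyzed_min = x$analyzed_min,
             rate_per_min = x$rate_per_min,
             median_duration_ms = x$median_duration_ms,
             median_ibi_ms = x$median_ibi_ms,
             median_peak_amp = x$median_peak_amp)
}

#' Detect bursts across a cohort at one fixed threshold
#'
#' Maps the filter -> envelope -> detect -> summarize chain over every
#' record of a cohort with a single fixed multiplier k.
#'
#' @param cohort A `cohort` (from [gen_cohort()]) or a list of records, each
#'   with `signal`, `subject_id`, `group`, `session`.
#' @param k Fixed threshold multiplier.
#' @param config Pipeline configuration (see [default_config()]); controls
#'   band edges, trim, and threshold mode.
#' @param envelopes Optional pre-computed list of [envelope]s aligned with
#'   the records, to skip re-filtering.
#' @return List with `summaries` (list of `subject_burst_summary`),
#'   `summary_table` (one row per record), and `events` (long per-event
#'   data frame).
#' @export
detect_cohort <- function(cohort, k, config = default_config(), envelopes = NULL) {
  records <- if (inherits(cohort, "cohort")) cohort$records else cohort
  if (is.null(envelopes)) envelopes <- cohort_envelopes(records, config)
  summaries <- vector("list", length(records))
  ev_rows <- vector("list", length(records))
  for (i in seq_along(records)) {
    rec <- records[[i]]
    ev <- detect_events(envelopes[[i]], k,
                        center = config$threshold$center,
                        mode = config$threshold$mode)
    summaries[[i]] <- summarize_subject(ev, envelopes[[i]],
                                        subject = rec$subject_id,
                                        group = rec$group,
                                        session = rec$session)
    if (nrow(ev)) {
      ev_rows[[i]] <- cbind(data.frame(subject = rec$subject_id,
                                       group = rec$group,
                                       session = rec$session), ev)
    }
  }
  list(summaries = summaries,
       summary_table = do.call(rbind, lapply(summaries, as.data.frame)),
       events = if (length(e <- Filter(Negate(is.null), ev_rows))) do.call(rbind, e)
                else NULL)
}

#' Compute envelopes for a list of records
#'
#' Convenience wrapper: beta band-pass + Hilbert envelope per record, with
#' parameters taken from the pipeline config.
#'
#' @param records List of records each containing a `signal` [time_series].
#' @param config Pipeline configuration list.
#' @return List of [envelope]s.
#' @export
cohort_envelopes <- function(records, config = default_config()) {
  lapply(records, function(rec) {
    filt <- bandpass_beta(rec$signal,
                          low = config$band$low, high = config$band$high,
                          trans_low = config$band$trans_low,
                          trans_high = config$band$trans_high)
    hilbert_envelope(filt, edge_trim_s = config$envelope$edge_trim_s)
  })
}
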