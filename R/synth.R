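#' Burst generator specification
#'
#' Parameters of the planted transient beta events: a homogeneous Poisson
#' process of Gaussian-windowed sinusoids. The envelope of each event is a
#' Gaussian whose full width at half maximum equals the drawn duration, so
#' the half-max duration measured downstream has an analytic oracle. The
#' defaults are the published resting-state conditions: ~75 ms events at
#' 13-30 Hz carriers, unit-order amplitude in noise-SD units.
#'
#' @param rate_per_min Expected events per minute (>= 0).
#' @param duration_ms_mean,duration_ms_sd Event envelope FWHM, ms (normal,
#'   truncated below at 20 ms).
#' @param amplitude_mean,amplitude_sd Event peak amplitude in signal units
#'   (normal, truncated at 0).
#' @param freq_low,freq_high Carrier frequency range, Hz (uniform draw).
#' @return A `burst_gen_spec`.
#' @export
burst_gen_spec <- function(rate_per_min = 110,
                           duration_ms_mean = 75, duration_ms_sd = 25,
                           amplitude_mean = 1, amplitude_sd = 0.4,
                           freq_low = 13, freq_high = 30) {
  if (rate_per_min < 0) stop("rate_per_min must be >= 0")
  if (duration_ms_mean <= 0) stop("duration_ms_mean must be > 0")
  if (freq_low >= freq_high) stop("freq_low must be < freq_high")
  if (amplitude_mean < 0 || amplitude_sd < 0) stop("amplitudes must be >= 0")
  structure(as.list(environment()), class = "burst_gen_spec")
}

#' Aperiodic (1/f) noise specification
#'
#' @param exponent Power-law exponent chi >= 0 of the PSD ~ f^-chi.
#' @param scale Standard deviation of the generated samples, signal units.
#' @param fs Sampling frequency, Hz.
#' @param duration_s Record duration, seconds.
#' @return A `noise_gen_spec`.
#' @export
noise_gen_spec <- function(exponent = 0.8, scale = 1, fs = 1000, duration_s = 180) {
  if (fs <= 0 || duration_s <= 0) stop("fs and duration_s must be positive")
  if (exponent < 0) stop("exponent must be >= 0")
  structure(as.list(environment()), class = "noise_gen_spec")
}

#' Group specification for cohort simulation
#'
#' Subject-level burst rates are drawn from Normal(rate_mean, rate_sd),
#' truncated at 0. Defaults follow the published group distributions:
#' patients 106 (SD 8) and controls 120 (SD 11) bursts/min in session 1.
#'
#' @param label `"patient"` or `"control"`.
#' @param n_subjects Number of subjects (>= 1).
#' @param rate_mean,rate_sd Subject-level burst-rate distribution, bursts/min.
#' @param noise A [noise_gen_spec].
#' @param burst A [burst_gen_spec]; its `rate_per_min` is overridden per
#'   subject by the drawn rate.
#' @return A `group_spec`.
#' @export
group_spec <- function(label = c("patient", "control"), n_subjects = 19,
                       rate_mean = if (match.arg(label) == "patient") 106 else 120,
                       rate_sd = if (match.arg(label) == "patient") 8 else 11,
                       noise = noise_gen_spec(
                         exponent = if (match.arg(label) == "patient") 0.8 else 0.6),
                       burst = burst_gen_spec()) {
  label <- match.arg(label)
  if (n_subjects < 1) stop("n_subjects must be >= 1")
  if (rate_sd < 0) stop("rate_sd must be >= 0")
  structure(list(label = label, n_subjects = n_subjects, rate_mean = rate_mean,
                 rate_sd = rate_sd, noise = noise, burst = burst),
            class = "group_spec")
}

#' Symptom score generator specification
#'
#' Scores are drawn as score ~ Poisson(exp(intercept_log + beta * rate))
#' with beta = log(1 + pct_change_per_10 / 100) / 10, i.e. the expected
#' score changes by `pct_change_per_10` percent for every +10 bursts/min.
#'
#' @param intercept_log Log expected score at rate 0. Usually set via
#'   `mean_at_ref`/`ref_rate` instead.
#' @param pct_change_per_10 Percent change in expected score per +10
#'   bursts/min (must be > -100; negative = decrease).
#' @param mean_at_ref,ref_rate Convenience parameterization: expected score
#'   `mean_at_ref` at burst rate `ref_rate`; used when `intercept_log` is NULL.
#' @return A `symptom_gen_spec` with fields `intercept_log`, `beta`,
#'   `pct_change_per_10`.
#' @export
symptom_gen_spec <- function(pct_change_per_10, intercept_log = NULL,
                             mean_at_ref = 10, ref_rate = 106) {
  if (pct_change_per_10 <= -100) stop("pct_change_per_10 must be > -100")
  beta <- log(1 + pct_change_per_10 / 100) / 10
  if (is.null(intercept_log)) intercept_log <- log(mean_at_ref) - beta * ref_rate
  structure(list(intercept_log = intercept_log, beta = beta,
                 pct_change_per_10 = pct_change_per_10),
            class = "symptom_gen_spec")
}

## frequency-domain shaping of white noise; assumes RNG state already set
.noise_core <- function(n, fs, chi, scale) {
  nf <- n %/% 2
  freqs <- (1:nf) * fs / n
  amp <- freqs^(-chi / 2)
  re <- stats::rnorm(nf)
  im <- stats::rnorm(nf)
  full <- complex(length.out = n)          # DC bin stays zero
  full[2:(nf + 1)] <- complex(real = re, imaginary = im) * amp
  if (n %% 2 == 0) full[nf + 1] <- complex(real = re[nf] * amp[nf])
  if (nf >= 2) full[n:(n - nf + 2)] <- Conj(full[2:nf])
  x <- Re(stats::fft(full, inverse = TRUE)) / n
  x / stats::sd(x) * scale
}

#' Generate aperiodic 1/f noise
#'
#' Colored noise with expected PSD proportional to f^-chi, synthesized by
#' frequency-domain shaping of white Gaussian noise (amplitude ~ f^(-chi/2),
#' DC bin zeroed), then rescaled to the requested standard deviation.
#' Identical seeds give bit-identical output.
#'
#' @param spec A [noise_gen_spec].
#' @param seed Integer RNG seed.
#' @return A [time_series] of `duration_s * fs` samples.
#' @export
gen_aperiodic_noise <- function(spec, seed) {
  stopifnot(inherits(spec, "noise_gen_spec"))
  set.seed(seed)
  n <- round(spec$duration_s * spec$fs)
  time_series(.noise_core(n, spec$fs, spec$exponent, spec$scale), fs = spec$fs)
}

## burst train core; assumes RNG state set; returns list(samples, events)
.burst_core <- function(spec, fs, duration_s) {
  n <- round(duration_s * fs)
  x <- numeric(n)
  n_ev <- stats::rpois(1, spec$rate_per_min * duration_s / 60)
  if (n_ev == 0) {
    return(list(samples = x,
                events = data.frame(onset_s = numeric(0), duration_s = numeric(0),
                                    amplitude = numeric(0), freq_hz = numeric(0))))
  }
  t0s <- sort(stats::runif(n_ev, 0, duration_s))
  freqs <- stats::runif(n_ev, spec$freq_low, spec$freq_high)
  durs <- pmax(stats::rnorm(n_ev, spec$duration_ms_mean, spec$duration_ms_sd), 20) / 1000
  amps <- pmax(stats::rnorm(n_ev, spec$amplitude_mean, spec$amplitude_sd), 0)
  phases <- stats::runif(n_ev, 0, 2 * pi)
  fwhm_to_sigma <- 1 / (2 * sqrt(2 * log(2)))
  t <- seq_len(n) / fs
  for (j in seq_len(n_ev)) {
    sigma <- durs[j] * fwhm_to_sigma
    idx <- which(abs(t - t0s[j]) < 4 * sigma)
    if (!length(idx)) next
    dt <- t[idx] - t0s[j]
    x[idx] <- x[idx] + amps[j] * exp(-dt^2 / (2 * sigma^2)) *
      sin(2 * pi * freqs[j] * dt + phases[j])
  }
  list(samples = x,
       events = data.frame(onset_s = t0s, duration_s = durs,
                           amplitude = amps, freq_hz = freqs))
}

#' Generate a train of transient beta events
#'
#' Event onsets follow a homogeneous Poisson process; each event is a
#' sinusoid at a frequency drawn uniformly in `[freq_low, freq_high]`,
#' windowed by a Gaussian whose FWHM equals the drawn duration. `onset_s` in
#' the truth table is the event center time.
#'
#' @param spec A [burst_gen_spec].
#' @param fs Sampling frequency, Hz.
#' @param duration_s Record length, seconds.
#' @param seed Integer RNG seed.
#' @return List with `ts` (a [time_series]) and `events` (truth data frame
#'   with onset_s, duration_s, amplitude, freq_hz).
#' @export
gen_burst_train <- function(spec, fs, duration_s, seed) {
  stopifnot(inherits(spec, "burst_gen_spec"))
  set.seed(seed)
  core <- .burst_core(spec, fs, duration_s)
  list(ts = time_series(core$samples, fs = fs), events = core$events)
}

#' Generate one synthetic subject record
#'
#' Draws the subject's burst rate from the group's Normal(rate_mean, rate_sd)
#' truncated at 0, then superimposes a burst train at that rate on 1/f noise.
#'
#' @param gspec A [group_spec].
#' @param subject_id Character subject identifier.
#' @param session Session number (1 or 2).
#' @param seed Integer RNG seed.
#' @param rate Optional fixed subject rate (bursts/min); when supplied the
#'   rate draw is skipped (used to share a subject-level rate across sessions).
#' @return A list of class `synthetic_subject`: subject_id, group, session,
#'   signal ([time_series]), truth_events, truth_rate (events/min).
#' @export
gen_subject <- function(gspec, subject_id, session = 1, seed = 1, rate = NULL) {
  stopifnot(inherits(gspec, "group_spec"))
  set.seed(seed)
  if (is.null(rate)) rate <- max(stats::rnorm(1, gspec$rate_mean, gspec$rate_sd), 0)
  bspec <- gspec$burst
  bspec$rate_per_min <- rate
  nspec <- gspec$noise
  n <- round(nspec$duration_s * nspec$fs)
  noise <- .noise_core(n, nspec$fs, nspec$exponent, nspec$scale)
  bursts <- .burst_core(bspec, nspec$fs, nspec$duration_s)
  structure(list(subject_id = subject_id, group = gspec$label, session = session,
                 signal = time_series(noise + bursts$samples, fs = nspec$fs),
                 truth_events = bursts$events,
                 truth_rate = nrow(bursts$events) / (nspec$duration_s / 60)),
            class = "synthetic_subject")
}

#' Generate a synthetic cohort
#'
#' Two sessions per subject by default: session 2 regenerates noise and
#' events with a new derived seed but keeps the subject-level rate (plus an
#' optional additive session offset, default 0 — the published data showed
#' no conclusive session effect on rate).
#'
#' @param groups List of [group_spec]s.
#' @param sessions Number of sessions per subject.
#' @param seed Master integer seed; all subject/session seeds derive from it.
#' @param session_rate_offset Additive change in bursts/min applied from
#'   session 2 onward.
#' @return An object of class `cohort`: `manifest` data frame (subject,
#'   group, session, truth_rate, truth_n_events) and `records`, a list of
#'   `synthetic_subject`s aligned with the manifest rows.
#' @export
gen_cohort <- function(groups, sessions = 2, seed = 1, session_rate_offset = 0) {
  if (!length(groups)) {
    return(structure(list(manifest = data.frame(subject = character(0),
                                                group = character(0),
                                                session = integer(0),
                                                truth_rate = numeric(0),
                                                truth_n_events = integer(0)),
                          records = list()), class = "cohort"))
  }
  ids <- unlist(lapply(groups, function(g)
    sprintf("%s_%02d", substr(g$label, 1, 4), seq_len(g$n_subjects))))
  if (anyDuplicated(ids)) stop("duplicate subject IDs across groups")
  records <- list()
  rows <- list()
  subj_idx <- 0
  for (g in groups) {
    for (i in seq_len(g$n_subjects)) {
      subj_idx <- subj_idx + 1
      id <- sprintf("%s_%02d", substr(g$label, 1, 4), i)
      set.seed(derive_seed(seed, 1L, subj_idx))
      rate1 <- max(stats::rnorm(1, g$rate_mean, g$rate_sd), 0)
      for (s in seq_len(sessions)) {
        rate_s <- max(rate1 + (s > 1) * session_rate_offset, 0)
        rec <- gen_subject(g, id, session = s,
                           seed = derive_seed(seed, 2L, subj_idx * 10L + s),
                           rate = rate_s)
        records[[length(records) + 1]] <- rec
        rows[[length(rows) + 1]] <- data.frame(
          subject = id, group = g$label, session = s,
          truth_rate = rec$truth_rate,
          truth_n_events = nrow(rec$truth_events))
      }
    }
  }
  structure(list(manifest = do.call(rbind, rows), records = records),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d records (%d subjects, %d sessions)\n",
              nrow(x$manifest), length(unique(x$manifest$subject)),
              length(unique(x$manifest$session))))
  invisible(x)
}

#' Derive a stage sub-seed from a master seed
#'
#' Stable scheme (documented so stages can be re-run in isolation):
#' `(master * 7919 + stage * 1009 + index) mod (2^31 - 1)`.
#'
#' @param master Master integer seed.
#' @param stage Integer stage code.
#' @param index Integer record index.
#' @return Integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master, stage = 0L, index = 0L) {
  as.integer((as.numeric(master) * 7919 + as.numeric(stage) * 1009 +
                as.numeric(index)) %% 2147483647)
}

#' Generate synthetic clinical factor scores
#'
#' Draws Poisson-distributed MDS-UPDRS-III-like factor scores linked to the
#' burst rate: score ~ Poisson(exp(intercept_log + beta * rate)).
#'
#' @param rates Data frame with columns `subject`, `session`, `rate_per_min`.
#' @param specs Named list of [symptom_gen_spec]s, one per clinical factor.
#' @param seed Integer RNG seed.
#' @return Data frame: subject, session, then one integer score column per
#'   factor.
#' @export
gen_clinical_scores <- function(rates, specs = default_symptom_specs(), seed = 1) {
  stopifnot(all(c("subject", "session", "rate_per_min") %in% names(rates)))
  if (any(rates$rate_per_min < 0)) stop("rates must be >= 0")
  set.seed(seed)
  out <- rates[, c("subject", "session")]
  for (nm in names(specs)) {
    sp <- specs[[nm]]
    stopifnot(inherits(sp, "symptom_gen_spec"))
    mu <- exp(sp$intercept_log + sp$beta * rates$rate_per_min)
    out[[nm]] <- stats::rpois(nrow(rates), mu)
  }
  out
}

#' Default clinical-factor generator specifications
#'
#' Six motor factors with expected severities emulating a moderate
#' Parkinson's cohort (MDS-UPDRS-III total ~ 30 off medication) and the
#' published burst-rate effects planted for bradykinesia (-28% per +10
#' bursts/min) and postural/kinetic tremor (-40% per +10 bursts/min); the
#' remaining factors are rate-independent.
#'
#' @return Named list of [symptom_gen_spec]s.
#' @export
default_symptom_specs <- function() {
  list(
    midline          = symptom_gen_spec(0,   mean_at_ref = 5),
    rest_tremor      = symptom_gen_spec(0,   mean_at_ref = 3),
    rigidity         = symptom_gen_spec(0,   mean_at_ref = 6),
    bradykinesia     = symptom_gen_spec(-28, mean_at_ref = 12),
    postural_tremor  = symptom_gen_spec(-40, mean_at_ref = 4),
    lower_limb       = symptom_gen_spec(0,   mean_at_ref = 3)
  )
}
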