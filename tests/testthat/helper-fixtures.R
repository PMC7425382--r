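# fixtures are generated in code; nothing is read from disk

# small cohort configuration for fast end-to-end tests
small_config <- function(n_subjects = 3, duration_s = 30, k_step = 0.5) {
  cfg <- default_config()
  cfg$synth$n_subjects <- n_subjects
  cfg$synth$duration_s <- duration_s
  cfg$threshold$k_step <- k_step
  cfg
}

# envelope with a small positive floor plus Gaussian bumps (peak amplitude
# above the floor, FWHM = 2.355 * sigma_s)
bump_envelope <- function(bumps, fs = 1000, dur_s = 10, floor = 0.01) {
  t <- seq(0, dur_s - 1 / fs, by = 1 / fs)
  mag <- rep(floor, length(t))
  for (b in bumps) {
    mag <- mag + b$peak * exp(-(t - b$at)^2 / (2 * b$sigma^2))
  }
  envelope(mag, fs = fs, band = c(13, 30))
}

# random non-negative envelope (smoothed absolute noise) for property tests
random_envelope <- function(seed, n = 4000, fs = 400) {
  set.seed(seed)
  x <- stats::filter(rnorm(n + 200), rep(1 / 30, 30), sides = 2)
  x <- abs(x[!is.na(x)])
  envelope(x, fs = fs, band = c(13, 30))
}

# group specs matching a (small) config, patient + control
.mini_groups <- function(cfg) {
  sy <- cfg$synth
  lapply(c("patient", "control"), function(lab) {
    g <- sy[[lab]]
    group_spec(lab, n_subjects = sy$n_subjects,
               rate_mean = g$rate_mean, rate_sd = g$rate_sd,
               noise = noise_gen_spec(exponent = g$exponent, fs = sy$fs,
                                      duration_s = sy$duration_s),
               burst = do.call(burst_gen_spec, sy$burst))
  })
}

# per-record burst summary table simulated at the count level (no signals),
# for model-recovery tests
simulate_rate_table <- function(n_per_group = 19, patient_mean = 106,
                                control_mean = 120, patient_sd = 8,
                                control_sd = 11, sessions = 2,
                                minutes = 3, seed = 1) {
  set.seed(seed)
  rows <- list()
  for (g in c("patient", "control")) {
    mu <- if (g == "patient") patient_mean else control_mean
    sdv <- if (g == "patient") patient_sd else control_sd
    for (i in seq_len(n_per_group)) {
      rate_i <- max(rnorm(1, mu, sdv), 1)
      for (s in seq_len(sessions)) {
        rows[[length(rows) + 1]] <- data.frame(
          subject = sprintf("%s_%02d", g, i), group = g, session = s,
          n_bursts = rpois(1, rate_i * minutes), analyzed_min = minutes)
      }
    }
  }
  out <- do.call(rbind, rows)
  out$rate_per_min <- out$n_bursts / out$analyzed_min
  out
}
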