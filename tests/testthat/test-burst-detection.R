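test_that("detection rejects invalid inputs and subthreshold envelopes", {
  env <- envelope(rep(1, 1000), fs = 100, band = c(13, 30))
  expect_error(detect_events(env, k = 0.5), ">= 1")
  expect_equal(nrow(detect_events(env, k = 2)), 0)   # nothing suprathreshold
})

test_that("half-max duration matches the Gaussian FWHM oracle within 2 ms", {
  sigma <- 0.030
  env <- bump_envelope(list(list(at = 5, peak = 3, sigma = sigma)))
  ev <- detect_events(env, k = 2)
  expect_equal(nrow(ev), 1)
  fwhm <- 2 * sqrt(2 * log(2)) * sigma
  expect_lt(abs(ev$duration_s - fwhm), 0.002)
  expect_equal(ev$peak_time_s, 5, tolerance = 0.002)
  expect_equal(ev$peak_amp, 3 + 0.01, tolerance = 1e-6)

  # several isolated bumps, several widths
  sigmas <- c(0.02, 0.04, 0.06)
  env2 <- bump_envelope(lapply(seq_along(sigmas), function(i)
    list(at = 2 * i, peak = 2 + i / 2, sigma = sigmas[i])), dur_s = 8)
  ev2 <- detect_events(env2, k = 3)
  expect_equal(nrow(ev2), 3)
  expect_true(all(abs(ev2$duration_s - 2 * sqrt(2 * log(2)) * sigmas) < 0.002))
})

test_that("event count is non-increasing in the threshold multiplier", {
  for (seed in 1:8) {
    env <- random_envelope(seed)
    counts <- vapply(seq(1, 5, by = 0.5),
                     function(k) nrow(detect_events(env, k)), numeric(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("detection is scale-invariant and events are disjoint", {
  env <- random_envelope(99)
  ev1 <- detect_events(env, 2)
  env_scaled <- envelope(env$magnitude * 7.3, fs = env$fs, band = env$band)
  ev2 <- detect_events(env_scaled, 2)
  expect_equal(ev1$onset_s, ev2$onset_s)
  expect_equal(ev1$peak_time_s, ev2$peak_time_s)
  expect_equal(ev2$peak_amp, 7.3 * ev1$peak_amp, tolerance = 1e-12)

  # disjoint half-max windows; total suprathreshold time below record length
  expect_true(all(diff(ev1$onset_s) > 0))
  expect_true(all(ev1$onset_s[-1] >= ev1$offset_s[-nrow(ev1)]))
  expect_lt(sum(ev1$duration_s), length(env$magnitude) / env$fs)
})

test_that("overlapping half-max windows merge keeping the larger peak", {
  env <- bump_envelope(list(list(at = 5.00, peak = 2.0, sigma = 0.05),
                            list(at = 5.08, peak = 3.0, sigma = 0.05)))
  ev <- detect_events(env, 2)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$peak_time_s, 5.08, tolerance = 0.02)
})

test_that("edge-truncated events are discarded", {
  # bump centered at the very start: its left half-max crossing is cut off
  env <- bump_envelope(list(list(at = 0, peak = 3, sigma = 0.05),
                            list(at = 5, peak = 3, sigma = 0.05)))
  ev <- detect_events(env, 2)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$peak_time_s, 5, tolerance = 0.01)
})

test_that("additive mode and alternative centers shift the threshold", {
  env <- random_envelope(5)
  # additive T = (1+k)*median is stricter than multiplicative at the same k
  n_mult <- nrow(detect_events(env, 2, mode = "multiplicative"))
  n_add <- nrow(detect_events(env, 2, mode = "additive"))
  expect_lte(n_add, n_mult)
  # mean/mode centers run without error and give plausible counts
  expect_gte(nrow(detect_events(env, 2, center = "mean")), 0)
  expect_gte(nrow(detect_events(env, 2, center = "mode")), 0)
})

test_that("subject summaries compute the four features correctly", {
  env <- envelope(rep(0.1, 180 * 100), fs = 100, band = c(13, 30))
  # 360 events in exactly 180 s -> rate 120/min
  ev <- data.frame(onset_s = seq(0.1, by = 0.499, length.out = 360))
  ev$offset_s <- ev$onset_s + 0.05
  ev$peak_time_s <- ev$onset_s + 0.025
  ev$peak_amp <- 1
  ev$duration_s <- 0.05
  su <- summarize_subject(ev, env, subject = "s", group = "control", session = 1)
  expect_equal(su$rate_per_min, 120)
  expect_equal(length(su$ibis_ms), 359)

  # worked IBI arithmetic: offset 1.000 s, next onset 1.199 s -> 199 ms
  e2 <- data.frame(onset_s = c(0.9, 1.199), offset_s = c(1.0, 1.31),
                   peak_time_s = c(0.95, 1.25), peak_amp = c(1, 1),
                   duration_s = c(0.1, 0.111))
  s2 <- summarize_subject(e2, env)
  expect_equal(s2$ibis_ms, 199)

  # zero events
  s0 <- summarize_subject(detect_events(envelope(rep(1, 1000), fs = 100,
                                                 band = c(13, 30)), 2), env)
  expect_equal(s0$rate_per_min, 0)
  expect_equal(length(s0$durations_ms), 0)
})

test_that("threshold optimization picks the amplitude-coupled threshold", {
  # single-k grid: k_star is that k
  envs <- lapply(1:2, function(s) random_envelope(s, n = 8000))
  tg1 <- suppressWarnings(optimize_threshold(envs, k_grid = 2.0,
                                             segment_len_s = 2))
  expect_equal(tg1$k_star, 2.0)
  expect_error(optimize_threshold(envs[1]), "2 subjects")

  # seeded mini-cohort with planted bursts: interior optimum beats the
  # grid extremes
  cfg <- small_config(n_subjects = 3, duration_s = 30)
  co <- gen_cohort(.mini_groups(cfg), sessions = 1, seed = 21)
  envs2 <- cohort_envelopes(co$records, cfg)
  tg <- suppressWarnings(optimize_threshold(envs2, k_grid = seq(1, 5, 0.5)))
  r <- tg$mean_r
  expect_gt(max(r, na.rm = TRUE), r[1])
  expect_gt(max(r, na.rm = TRUE), r[length(r)] + ifelse(is.na(r[length(r)]), -Inf, 0))
  expect_true(tg$k_star > 1 && tg$k_star < 5)
})

test_that("cohort detection recovers planted rates at high SNR", {
  # strong, well-separated bursts: detected rate tracks the planted rate
  g <- group_spec("patient", n_subjects = 6, rate_mean = 60, rate_sd = 25,
                  noise = noise_gen_spec(exponent = 0.8, scale = 0.2,
                                         fs = 500, duration_s = 40),
                  burst = burst_gen_spec(duration_ms_mean = 90,
                                         duration_ms_sd = 10,
                                         amplitude_mean = 2, amplitude_sd = 0.2))
  co <- gen_cohort(list(g), sessions = 1, seed = 31)
  det <- detect_cohort(co, k = 2.5, config = default_config())
  st <- det$summary_table
  truth <- co$manifest$truth_rate
  expect_equal(nrow(st), 6)
  expect_gt(cor(st$rate_per_min, truth), 0.9)

  # per-subject counts at the grid maximum never exceed counts at lower k
  det5 <- detect_cohort(co, k = 5, config = default_config())
  expect_true(all(det5$summary_table$n_bursts <= st$n_bursts))
})
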