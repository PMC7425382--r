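test_that("percent-change transform round-trips exactly", {
  for (b in c(-0.5, -0.1, 0, 0.2, 1)) {
    expect_equal(pct_to_coef(pct_change(b)), b, tolerance = 1e-12)
  }
  expect_equal(pct_change(log(0.72)), -28, tolerance = 1e-10)
})

test_that("exceedance probability behaves like a posterior tail", {
  expect_equal(exceedance_prob(0, 1), 0.5)
  expect_lt(exceedance_prob(5, 1, method = "analytic"), 0.001)
  expect_equal(exceedance_prob(1.2, 0.8, method = "analytic"),
               pnorm(-1.5), tolerance = 1e-12)
  # Monte-Carlo agrees with the analytic Gaussian tail
  mc <- exceedance_prob(1.0, 0.7, n_draws = 20000, seed = 4)
  expect_lt(abs(mc - pnorm(-1 / 0.7)), 0.02)
  expect_error(exceedance_prob(1, 0), "degenerate")
  expect_error(exceedance_prob(samples = rep(2, 10)), "degenerate")
})

test_that("BIC Bayes factor is exact for self-comparison and penalizes noise", {
  d <- simulate_rate_table(n_per_group = 10, seed = 2)
  m <- lme4::glmer(n_bursts ~ group + (1 | subject), data = d, family = poisson)
  expect_identical(approx_bf(m, m), 1)

  # adding a pure-noise covariate loses evidence in the median across seeds
  bfs <- vapply(1:7, function(s) {
    set.seed(100 + s)
    d$noise_cov <- rnorm(nrow(d))
    m1 <- suppressMessages(lme4::glmer(n_bursts ~ group + noise_cov + (1 | subject),
                                       data = d, family = poisson))
    approx_bf(m1, m)
  }, numeric(1))
  expect_lt(median(bfs), 1)
})

test_that("rate model finds no group effect when groups are identical", {
  d <- simulate_rate_table(n_per_group = 12, patient_mean = 110,
                           control_mean = 110, patient_sd = 5, control_sd = 5,
                           seed = 5)
  # make the two groups' counts literally identical, subject for subject
  pat <- d[d$group == "patient", ]
  ctrl <- pat
  ctrl$group <- "control"
  ctrl$subject <- sub("patient", "control", ctrl$subject)
  d <- rbind(pat, ctrl)
  res <- suppressMessages(fit_rate_model(d))
  grp <- res$contrasts[grepl("^group", res$contrasts$term), ]
  expect_lt(abs(grp$pct), 5)
  expect_true(grp$pct_lo < 0 && grp$pct_hi > 0)
  expect_lt(res$bf_group, 1)
})

test_that("rate model recovers a planted group deficit", {
  # patients 15% below controls
  d <- simulate_rate_table(n_per_group = 30, patient_mean = 102,
                           control_mean = 120, patient_sd = 8, control_sd = 8,
                           seed = 11)
  res <- fit_rate_model(d)
  grp <- res$contrasts[grepl("^group", res$contrasts$term), ]
  planted <- 100 * (102 / 120 - 1)
  # contrast is patient -> control or control -> patient depending on level
  # order; factor levels are alphabetical so the contrast is 'patient'
  expect_true(grp$pct_lo < planted + 12 && grp$pct_hi > planted - 12)
  expect_true(sign(grp$pct) == sign(planted))
  expect_gt(res$bf_group, 3)

  # single group: contrast absent, no failure
  one <- fit_rate_model(d[d$group == "patient", ])
  expect_true(is.na(one$bf_group))
})

test_that("group-rate contrast has near-nominal coverage and small bias", {
  n_sim <- 60
  planted_log <- log(106 / 120)
  hits <- 0
  ests <- numeric(n_sim)
  for (s in seq_len(n_sim)) {
    d <- simulate_rate_table(n_per_group = 19, patient_mean = 106,
                             control_mean = 120, patient_sd = 8,
                             control_sd = 11, seed = 1000 + s)
    res <- suppressMessages(fit_rate_model(d))
    grp <- res$contrasts[grepl("^group", res$contrasts$term), ]
    ests[s] <- grp$estimate
    if (pct_to_coef(grp$pct_lo) < planted_log &&
        pct_to_coef(grp$pct_hi) > planted_log) hits <- hits + 1
  }
  expect_lt(abs(pct_change(mean(ests)) - pct_change(planted_log)), 2)
  expect_gte(hits / n_sim, 0.90)
  expect_lte(hits / n_sim, 0.99)
})

test_that("feature model detects planted lognormal shifts and nests cleanly", {
  set.seed(7)
  mk_events <- function(n_sub, mu, group) {
    do.call(rbind, lapply(seq_len(n_sub), function(i) {
      subj_eff <- rnorm(1, 0, 0.05)
      do.call(rbind, lapply(1:2, function(s) {
        data.frame(value = rlnorm(40, mu + subj_eff, 0.4),
                   subject = sprintf("%s%02d", group, i),
                   group = group, session = s)
      }))
    }))
  }
  # identical values across groups: group effect exactly zero
  pat0 <- mk_events(8, log(200), "patient")
  ctl0 <- pat0
  ctl0$group <- "control"
  ctl0$subject <- sub("patient", "control", ctl0$subject)
  r0 <- fit_feature_model(rbind(pat0, ctl0), family = "lognormal")
  g0 <- r0$contrasts[grepl("^group", r0$contrasts$term), ]
  expect_lt(abs(g0$pct), 1e-6)
  expect_true(g0$pct_lo < 0 && g0$pct_hi > 0)

  # planted ~11% group difference in the median (patient / control = 200/180)
  d1 <- rbind(mk_events(10, log(200), "patient"), mk_events(10, log(180), "control"))
  r1 <- fit_feature_model(d1, family = "lognormal")
  g1 <- r1$contrasts[grepl("^group", r1$contrasts$term), ]
  planted <- 100 * (200 / 180 - 1)
  expect_true(g1$pct_lo < planted && g1$pct_hi > planted)
  expect_gt(g1$pct, 0)

  # shift fixed to 0 reduces the shifted model to the lognormal model
  r_shift0 <- fit_feature_model(d1, family = "shifted_lognormal", shift = 0)
  expect_equal(r_shift0$contrasts$estimate, r1$contrasts$estimate,
               tolerance = 1e-10)

  # profiled shift stays below the minimum and the model still fits
  r_prof <- fit_feature_model(d1, family = "shifted_lognormal")
  expect_lt(r_prof$shift, min(d1$value))
  expect_error(fit_feature_model(d1, family = "shifted_lognormal",
                                 shift = min(d1$value)), "non-positive")
})

test_that("symptom models recover planted burst-rate effects", {
  set.seed(13)
  n <- 30
  rates <- data.frame(
    subject = rep(sprintf("p%02d", 1:n), each = 2),
    session = rep(1:2, n),
    rate_per_min = pmax(rnorm(2 * n, 106, 10), 60))
  specs <- list(bradykinesia = symptom_gen_spec(-28, mean_at_ref = 12),
                flat = symptom_gen_spec(0, mean_at_ref = 6))
  scores <- gen_clinical_scores(rates, specs, seed = 17)
  summ <- cbind(rates, group = "patient")
  eff <- suppressWarnings(fit_symptom_models(summ, scores))
  brady <- eff[eff$factor == "bradykinesia", ]
  expect_true(brady$pct_lo < -28 && brady$pct_hi > -28)
  expect_lt(brady$p_prob, 0.05)
  flat <- eff[eff$factor == "flat", ]
  expect_true(flat$pct_lo < 0 && flat$pct_hi > 0)

  # doubling all scores leaves the slope essentially unchanged
  scores2 <- scores
  scores2$bradykinesia <- scores2$bradykinesia * 2L
  eff2 <- suppressWarnings(fit_symptom_models(summ, scores2,
                                              factors = "bradykinesia"))
  expect_equal(eff2$beta[1], brady$beta, tolerance = 0.01)

  # all-zero factor skipped with a warning
  scores$zero <- 0L
  expect_warning(fit_symptom_models(summ, scores), "all zero")
})
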