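#' Percent-change transform of a log-scale coefficient
#'
#' `pct_change(b) = 100 * (exp(b) - 1)`; [pct_to_coef()] is its exact
#' inverse.
#'
#' @param b Coefficient on the log scale.
#' @return Percent change.
#' @export
pct_change <- function(b) 100 * (exp(b) - 1)

#' @rdname pct_change
#' @param pct Percent change.
#' @export
pct_to_coef <- function(pct) log(1 + pct / 100)

#' Exceedance probability of a contrast
#'
#' Probability mass of the contrast's sign-opposite tail — the analogue of
#' checking whether the central 95% of a posterior excludes zero. Computed
#' either from Monte-Carlo draws from the contrast's asymptotic Gaussian
#' (default) or analytically from the Gaussian tail. Values near 0 indicate
#' evidence for a difference; a contrast centered at 0 gives ~0.5.
#'
#' @param estimate Point estimate of the contrast (ignored when `samples`
#'   given).
#' @param se Standard error (> 0).
#' @param samples Optional vector of draws of the contrast; overrides
#'   `estimate`/`se`.
#' @param n_draws Number of Monte-Carlo draws.
#' @param method `"mc"` (default) or `"analytic"`.
#' @param seed Optional RNG seed for the draws.
#' @return Probability in `[0, 1]`.
#' @export
exceedance_prob <- function(estimate = NULL, se = NULL, samples = NULL,
                            n_draws = 2000, method = c("mc", "analytic"),
                            seed = NULL) {
  method <- match.arg(method)
  if (is.null(samples)) {
    if (is.null(estimate) || is.null(se)) stop("supply estimate and se, or samples")
    if (se <= 0) stop("degenerate (zero-variance) contrast distribution")
    if (method == "analytic") return(stats::pnorm(-abs(estimate) / se))
    if (!is.null(seed)) set.seed(seed)
    samples <- stats::rnorm(n_draws, estimate, se)
    ref <- estimate
  } else {
    if (stats::sd(samples) == 0) stop("degenerate (zero-variance) contrast distribution")
    ref <- mean(samples)
  }
  if (ref == 0) return(0.5)
  mean(sign(samples) != sign(ref))
}

#' BIC-approximate Bayes factor between nested models
#'
#' `BF = exp((BIC_without - BIC_with) / 2)`, the Schwarz approximation to
#' the marginal-likelihood ratio of a model including a factor versus the
#' nested model without it. BF > 1 favours the richer model; on the
#' conventional scale BF > 3 / < 1/3 is conclusive evidence for / against.
#'
#' @param model_with,model_without Fitted (g)lmer or (g)lm models on
#'   identical data, `model_without` nested in `model_with`.
#' @return Positive scalar Bayes factor.
#' @export
approx_bf <- function(model_with, model_without) {
  n1 <- stats::nobs(model_with)
  n2 <- stats::nobs(model_without)
  if (n1 != n2) stop("models must be fitted to identical data")
  if (length(stats::coef(summary(model_with))[, 1]) <
      length(stats::coef(summary(model_without))[, 1]) &&
      !isTRUE(all.equal(stats::BIC(model_with), stats::BIC(model_without))))
    stop("model_without must be nested in model_with")
  exp((stats::BIC(model_without) - stats::BIC(model_with)) / 2)
}

## wald row -> list(estimate, se, pct, pct_ci, p_prob)
.contrast_row <- function(est, se, label) {
  ci <- est + c(-1, 1) * stats::qnorm(0.975) * se
  data.frame(term = label, estimate = est, se = se,
             pct = pct_change(est), pct_lo = pct_change(ci[1]),
             pct_hi = pct_change(ci[2]),
             p_prob = exceedance_prob(est, se, method = "analytic"))
}

#' Mixed-effects Poisson model of the burst rate
#'
#' Poisson GLMM (Laplace approximation) of per-record burst counts on Group
#' and Session with a subject random intercept and the analyzed minutes as
#' exposure offset. Bayes factors for Group, Session and their interaction
#' are BIC approximations from the nested-model comparisons; contrasts are
#' reported as percent rate differences with Wald CIs and exceedance
#' probabilities.
#'
#' @param summaries Data frame with columns `subject`, `group`, `session`,
#'   `n_bursts`, `analyzed_min` (a `summary_table` from [detect_cohort()]).
#' @return A list of class `model_result`: `contrasts` data frame,
#'   `bf_group`, `bf_session`, `bf_interaction`, `model` (the full fit).
#' @export
fit_rate_model <- function(summaries) {
  d <- as.data.frame(summaries)
  stopifnot(all(c("subject", "group", "session", "n_bursts", "analyzed_min") %in% names(d)))
  d$group <- factor(d$group)
  d$session <- factor(d$session)
  d$subject <- factor(d$subject)
  single_group <- nlevels(d$group) < 2
  single_session <- nlevels(d$session) < 2
  off <- log(d$analyzed_min)
  fit_f <- function(rhs) {
    lme4::glmer(stats::as.formula(paste("n_bursts ~", rhs, "+ (1 | subject)")),
                data = d, family = stats::poisson, offset = off,
                control = lme4::glmerControl(calc.derivs = FALSE))
  }
  rhs_full <- paste(c(if (!single_group) "group", if (!single_session) "session"),
                    collapse = " + ")
  if (rhs_full == "") rhs_full <- "1"
  m_full <- fit_f(rhs_full)
  cs <- stats::coef(summary(m_full))
  contrasts <- NULL
  bf_group <- bf_session <- bf_interaction <- NA_real_
  if (!single_group) {
    i <- grep("^group", rownames(cs))
    contrasts <- rbind(contrasts, .contrast_row(cs[i, 1], cs[i, 2],
                                                paste0("group:", levels(d$group)[2])))
    m_nog <- fit_f(if (single_session) "1" else "session")
    bf_group <- approx_bf(m_full, m_nog)
  }
  if (!single_session) {
    i <- grep("^session", rownames(cs))
    contrasts <- rbind(contrasts, .contrast_row(cs[i, 1], cs[i, 2],
                                                paste0("session:", levels(d$session)[2])))
    m_nos <- fit_f(if (single_group) "1" else "group")
    bf_session <- approx_bf(m_full, m_nos)
  }
  if (!single_group && !single_session) {
    m_int <- fit_f("group * session")
    bf_interaction <- approx_bf(m_int, m_full)
  }
  structure(list(contrasts = contrasts, bf_group = bf_group,
                 bf_session = bf_session, bf_interaction = bf_interaction,
                 model = m_full), class = "model_result")
}

#' @export
print.model_result <- function(x, ...) {
  cat("<model_result>\n")
  if (!is.null(x$contrasts)) {
    for (i in seq_len(nrow(x$contrasts))) {
      r <- x$contrasts[i, ]
      cat(sprintf("  %-18s %+6.1f%% (95%% CI %+.1f to %+.1f), P = %.3g\n",
                  r$term, r$pct, r$pct_lo, r$pct_hi, r$p_prob))
    }
  }
  cat(sprintf("  BF group %.3g | session %.3g | interaction %.3g\n",
              x$bf_group, x$bf_session, x$bf_interaction))
  invisible(x)
}

## profile the shift of a shifted-lognormal on a coarse grid
.profile_shift <- function(value, design_fit, grid_n = 25) {
  lo <- 0
  hi <- min(value) * 0.99
  if (hi <= 0) return(0)
  grid <- seq(lo, hi, length.out = grid_n)
  ll <- vapply(grid, function(s) {
    y <- log(value - s)
    m <- design_fit(y)
    as.numeric(stats::logLik(m)) - sum(y)   # Jacobian of log(value - s)
  }, numeric(1))
  grid[which.max(ll)]
}

#' Mixed-effects lognormal model of per-event burst features
#'
#' Regression of per-event values (durations, inter-burst intervals or peak
#' amplitudes) on Group and Session with a subject random intercept, on the
#' log scale: a lognormal model, or a shifted lognormal where the shift is
#' profiled on a coarse grid over `[0, 0.99 * min(value)]`. Effects are
#' reported as percent changes of the distribution's median (the lognormal
#' median is exp of the linear predictor).
#'
#' @param data Data frame with columns `value`, `subject`, `group`,
#'   `session` (one row per event).
#' @param family `"lognormal"` or `"shifted_lognormal"`.
#' @param shift Fixed shift; `NULL` (default) profiles it for the shifted
#'   family; 0 reduces exactly to the lognormal model.
#' @return A list of class `model_result` with `contrasts`, BFs, `shift`,
#'   `model`.
#' @export
fit_feature_model <- function(data, family = c("lognormal", "shifted_lognormal"),
                              shift = NULL) {
  family <- match.arg(family)
  d <- as.data.frame(data)
  stopifnot(all(c("value", "subject", "group", "session") %in% names(d)))
  d$group <- factor(d$group)
  d$session <- factor(d$session)
  d$subject <- factor(d$subject)
  if (family == "lognormal") shift <- 0
  fit_y <- function(y, rhs) {
    dd <- d
    dd$y <- y
    lme4::lmer(stats::as.formula(paste("y ~", rhs, "+ (1 | subject)")),
               data = dd, REML = FALSE)
  }
  if (family == "shifted_lognormal" && is.null(shift)) {
    shift <- .profile_shift(d$value, function(y) fit_y(y, "group + session"))
  }
  if (any(d$value <= shift)) stop("non-positive values after shift")
  y <- log(d$value - shift)
  m_full <- fit_y(y, "group + session")
  m_nog <- fit_y(y, "session")
  m_nos <- fit_y(y, "group")
  m_int <- fit_y(y, "group * session")
  cs <- stats::coef(summary(m_full))
  ig <- grep("^group", rownames(cs))
  is_ <- grep("^session", rownames(cs))
  contrasts <- rbind(
    .contrast_row(cs[ig, 1], cs[ig, 2], paste0("group:", levels(d$group)[2])),
    .contrast_row(cs[is_, 1], cs[is_, 2], paste0("session:", levels(d$session)[2])))
  structure(list(contrasts = contrasts,
                 bf_group = approx_bf(m_full, m_nog),
                 bf_session = approx_bf(m_full, m_nos),
                 bf_interaction = approx_bf(m_int, m_full),
                 shift = shift, model = m_full), class = "model_result")
}

#' Burst-rate regressions of clinical factor scores
#'
#' One mixed-effect Poisson regression per clinical factor: score modelled
#' as a linear function of the burst rate with subject and session random
#' intercepts (patients only). With only two sessions the session variance
#' is weakly identified; when the fit is singular in that variance the
#' model falls back to a fixed session effect (noted in the result). The
#' rate enters scaled by 10, so the reported effect is the percent change
#' in expected score per +10 bursts/min.
#'
#' @param summaries Data frame with `subject`, `session`, `rate_per_min`
#'   (e.g. a `summary_table` restricted to patients).
#' @param scores Clinical-score data frame: `subject`, `session`, one
#'   integer column per factor (see [gen_clinical_scores()]).
#' @param factors Factor columns to model; defaults to every non-id column
#'   of `scores`.
#' @return Data frame of class `symptom_effects`: factor, pct_change_per_10
#'   with CI, p_prob, beta (per burst/min), session_term used.
#' @export
fit_symptom_models <- function(summaries, scores, factors = NULL) {
  s <- as.data.frame(summaries)
  d <- merge(s[, c("subject", "session", "rate_per_min")], scores,
             by = c("subject", "session"))
  if (is.null(factors)) factors <- setdiff(names(scores), c("subject", "session"))
  d$subject <- factor(d$subject)
  d$session <- factor(d$session)
  d$rate10 <- (d$rate_per_min - mean(d$rate_per_min)) / 10
  rows <- list()
  for (f in factors) {
    if (all(d[[f]] == 0)) {
      warning(sprintf("factor '%s' is all zero; skipped", f))
      next
    }
    dd <- d
    dd$score <- d[[f]]
    m <- suppressMessages(
      lme4::glmer(score ~ rate10 + (1 | subject) + (1 | session),
                  data = dd, family = stats::poisson,
                  control = lme4::glmerControl(calc.derivs = FALSE)))
    session_term <- "random"
    vc <- as.data.frame(lme4::VarCorr(m))
    if (any(vc$sdcor[vc$grp == "session"] < 1e-6)) {
      m <- suppressMessages(
        lme4::glmer(score ~ rate10 + session + (1 | subject),
                    data = dd, family = stats::poisson,
                    control = lme4::glmerControl(calc.derivs = FALSE)))
      session_term <- "fixed"
    }
    cs <- stats::coef(summary(m))
    b10 <- cs["rate10", 1]
    se10 <- cs["rate10", 2]
    ci <- b10 + c(-1, 1) * stats::qnorm(0.975) * se10
    rows[[f]] <- data.frame(
      factor = f,
      pct_change_per_10 = pct_change(b10),
      pct_lo = pct_change(ci[1]), pct_hi = pct_change(ci[2]),
      p_prob = exceedance_prob(b10, se10, method = "analytic"),
      beta = b10 / 10, session_term = session_term)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("symptom_effects", "data.frame")
  out
}
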