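## midrank Mann-Whitney AUC: P(score of a positive > score of a negative),
## ties counted half
.auc_mw <- function(score, positive) {
  n1 <- sum(positive)
  n0 <- sum(!positive)
  r <- rank(score)   # midranks
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC analysis of one feature as a group classifier
#'
#' Univariate logistic regression of group on the feature; the AUC of the
#' fitted scores is computed exactly as the midrank Mann-Whitney statistic
#' (identical to the AUC of the raw feature up to the direction of the
#' fitted coefficient, since the logistic link is monotone). The optimal
#' cut-off is the feature value maximizing Youden's J (sensitivity +
#' specificity - 1; ties resolved to the lower value); an accuracy
#' criterion is available.
#'
#' @param values Numeric feature values, one per subject.
#' @param labels Group labels; `positive` names the class the classifier
#'   detects.
#' @param positive Label treated as the positive class (default
#'   `"patient"` when present, else the first level).
#' @param criterion `"youden"` (default) or `"accuracy"` for the optimal
#'   cut-off.
#' @return A list of class `roc_result`: `auc`, `optimal_threshold`,
#'   `direction` (+1 if the positive class has larger scores), `curve`
#'   (fpr/tpr points), `coef` (logistic slope).
#' @export
roc_for_feature <- function(values, labels, positive = NULL,
                            criterion = c("youden", "accuracy")) {
  criterion <- match.arg(criterion)
  ok <- !is.na(values)
  values <- values[ok]
  labels <- as.character(labels)[ok]
  ul <- unique(labels)
  if (length(ul) < 2) stop("both classes must be present")
  if (is.null(positive)) positive <- if ("patient" %in% ul) "patient" else ul[1]
  y <- labels == positive
  fit <- suppressWarnings(stats::glm(y ~ values, family = stats::binomial))
  b <- unname(stats::coef(fit)[2])
  if (is.na(b)) b <- 0
  score <- if (b >= 0) values else -values
  auc <- .auc_mw(score, y)
  ## empirical ROC over candidate cut-offs on the (oriented) feature
  cand <- sort(unique(score))
  cuts <- c(-Inf, cand)
  sens <- vapply(cuts, function(cc) mean(score[y] >= cc), numeric(1))
  spec <- vapply(cuts, function(cc) mean(score[!y] < cc), numeric(1))
  j <- switch(criterion, youden = sens + spec - 1,
              accuracy = (sens * sum(y) + spec * sum(!y)) / length(y))
  best <- which(j == max(j))
  best <- best[which.min(cuts[best])]   # tie -> lower cut
  thr <- cuts[best]
  if (b < 0 && is.finite(thr)) thr <- -thr
  ord <- order(1 - spec, sens)
  structure(list(auc = auc, optimal_threshold = unname(thr),
                 direction = if (b >= 0) 1 else -1,
                 curve = data.frame(fpr = (1 - spec)[ord], tpr = sens[ord]),
                 coef = b, positive = positive),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC %.3f, optimal threshold %.4g (direction %+d, positive = %s)\n",
              x$auc, x$optimal_threshold, x$direction, x$positive))
  invisible(x)
}

#' ROC table over all burst and spectral features, per session
#'
#' One ROC analysis per feature and session, mirroring the published
#' sensitivity/specificity table: relative beta power, 1/f intercept and
#' slope, beta peak power, burst rate, burst duration, inter-burst
#' interval, peak amplitude.
#'
#' @param burst_table Per-record burst summary table (from
#'   [detect_cohort()]'s `summary_table`).
#' @param spectral_table Per-record spectral feature table (from
#'   [spectral_cohort()]); optional.
#' @param criterion Optimal-threshold criterion, see [roc_for_feature()].
#' @return Data frame: feature, session, auc, optimal_threshold, n.
#' @export
roc_suite <- function(burst_table, spectral_table = NULL,
                      criterion = "youden") {
  feats <- list(
    burst_rate = c("burst", "rate_per_min"),
    burst_duration = c("burst", "median_duration_ms"),
    inter_burst_interval = c("burst", "median_ibi_ms"),
    peak_amplitude = c("burst", "median_peak_amp"))
  if (!is.null(spectral_table)) {
    feats <- c(list(
      relative_beta_power = c("spec", "relative_beta"),
      f1_intercept = c("spec", "intercept"),
      f1_slope = c("spec", "exponent"),
      beta_peak_power = c("spec", "beta_peak_power")), feats)
  }
  rows <- list()
  for (nm in names(feats)) {
    src <- if (feats[[nm]][1] == "burst") burst_table else spectral_table
    col <- feats[[nm]][2]
    if (!col %in% names(src)) {
      warning(sprintf("feature column '%s' missing; row skipped", col))
      next
    }
    for (sess in sort(unique(src$session))) {
      d <- src[src$session == sess, ]
      if (length(unique(d$group)) < 2 || all(is.na(d[[col]]))) next
      r <- roc_for_feature(d[[col]], d$group, criterion = criterion)
      rows[[length(rows) + 1]] <- data.frame(
        feature = nm, session = sess, auc = r$auc,
        optimal_threshold = r$optimal_threshold, n = sum(!is.na(d[[col]])))
    }
  }
  do.call(rbind, rows)
}

#' Burst-rate robustness analysis across thresholds
#'
#' Repeats the primary burst-rate comparison at every threshold of the
#' grid: per k, re-detect bursts, fit the mixed Poisson rate model, compute
#' the BIC-approximate Bayes factors for Group, Session and their
#' interaction, and the burst-rate AUC per session.
#'
#' @param cohort A `cohort` (or record list).
#' @param k_grid Ascending candidate multipliers.
#' @param config Pipeline configuration.
#' @param envelopes Optional pre-computed envelopes (recommended when
#'   sweeping many thresholds).
#' @return Data frame of class `threshold_sweep`: k, per-group mean rates,
#'   bf_group, bf_session, bf_interaction, auc per session.
#' @export
threshold_sweep <- function(cohort, k_grid = seq(1, 5, by = 0.1),
                            config = default_config(), envelopes = NULL) {
  records <- if (inherits(cohort, "cohort")) cohort$records else cohort
  if (is.null(envelopes)) envelopes <- cohort_envelopes(records, config)
  rows <- list()
  for (k in k_grid) {
    det <- detect_cohort(records, k, config, envelopes = envelopes)
    st <- det$summary_table
    mdl <- fit_rate_model(st)
    grp_means <- tapply(st$rate_per_min, st$group, mean)
    row <- data.frame(k = k,
                      rate_patient = unname(grp_means["patient"]),
                      rate_control = unname(grp_means["control"]),
                      bf_group = mdl$bf_group, bf_session = mdl$bf_session,
                      bf_interaction = mdl$bf_interaction)
    for (sess in sort(unique(st$session))) {
      d <- st[st$session == sess, ]
      row[[paste0("auc_session", sess)]] <-
        if (length(unique(d$group)) >= 2)
          roc_for_feature(d$rate_per_min, d$group)$auc else NA_real_
    }
    rows[[length(rows) + 1]] <- row
  }
  out <- do.call(rbind, rows)
  class(out) <- c("threshold_sweep", "data.frame")
  out
}
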