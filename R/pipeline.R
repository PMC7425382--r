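#' Default pipeline configuration
#'
#' Nested list of every tunable of the pipeline with its default. The
#' defaults are the published analysis settings (13-30 Hz band with
#' 3.25/7.5 Hz transitions, 1 s envelope trim, threshold grid 1-5 in steps
#' of 0.1 with 3 s segments, 3 s Welch segments with 50% overlap over
#' 1-48 Hz, at most 8 spectral peaks) and the synthetic cohort's study
#' conditions (19 + 19 subjects, two sessions, 3 min at 1000 Hz).
#'
#' @return Named nested list.
#' @export
default_config <- function() {
  list(
    band = list(low = 13, high = 30, trans_low = 3.25, trans_high = 7.5),
    envelope = list(edge_trim_s = 1),
    threshold = list(k_min = 1.0, k_max = 5.0, k_step = 0.1,
                     segment_len_s = 3.0, center = "median",
                     mode = "multiplicative"),
    psd = list(seg_len_s = 3.0, overlap = 0.5, fmin = 1, fmax = 48),
    fit = list(max_peaks = 8),
    stats = list(bootstrap_n = 2000),
    synth = list(n_subjects = 19, sessions = 2, fs = 1000, duration_s = 180,
                 patient = list(rate_mean = 106, rate_sd = 8, exponent = 0.8),
                 control = list(rate_mean = 120, rate_sd = 11, exponent = 0.6),
                 burst = list(duration_ms_mean = 75, duration_ms_sd = 25,
                              amplitude_mean = 1, amplitude_sd = 0.4,
                              freq_low = 13, freq_high = 30),
                 session_rate_offset = 0),
    seed = 1
  )
}

## deep-merge user config over defaults
.merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(user[[nm]]) && is.list(base[[nm]]))
      base[[nm]] <- .merge_config(base[[nm]], user[[nm]])
    else base[[nm]] <- user[[nm]]
  }
  base
}

#' Load a YAML pipeline configuration
#'
#' Reads a YAML file and merges it over [default_config()], so partial
#' configs are valid.
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @return Configuration list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) cfg <- .merge_config(cfg, yaml::read_yaml(path))
  cfg
}

## group specs implied by a config
.config_groups <- function(config) {
  sy <- config$synth
  bspec <- do.call(burst_gen_spec, sy$burst)
  mk <- function(label, g) {
    group_spec(label, n_subjects = sy$n_subjects,
               rate_mean = g$rate_mean, rate_sd = g$rate_sd,
               noise = noise_gen_spec(exponent = g$exponent, fs = sy$fs,
                                      duration_s = sy$duration_s),
               burst = bspec)
  }
  list(mk("patient", sy$patient), mk("control", sy$control))
}

#' Simulate the default synthetic cohort
#'
#' Builds the cohort the configuration describes (in memory), and
#' optionally writes signals, manifest, truth tables and the serialized
#' config to `out_dir`.
#'
#' @param config Configuration list.
#' @param seed Master seed (overrides `config$seed` when given).
#' @param out_dir Optional output directory; created if missing.
#' @param format Signal file format when writing: `"bin"` (raw
#'   little-endian float64 + YAML sidecar) or `"txt"` (single column).
#' @return A `cohort`; when `out_dir` is given, the manifest gains a `path`
#'   column pointing at the signal files.
#' @export
run_simulate <- function(config = default_config(), seed = NULL,
                         out_dir = NULL, format = c("bin", "txt")) {
  format <- match.arg(format)
  if (is.null(seed)) seed <- config$seed
  cohort <- gen_cohort(.config_groups(config), sessions = config$synth$sessions,
                       seed = seed,
                       session_rate_offset = config$synth$session_rate_offset)
  scores <- gen_clinical_scores(
    data.frame(subject = cohort$manifest$subject,
               session = cohort$manifest$session,
               rate_per_min = cohort$manifest$truth_rate)[cohort$manifest$group == "patient", ],
    seed = derive_seed(seed, 9L))
  cohort$clinical_scores <- scores
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
    paths <- character(nrow(cohort$manifest))
    for (i in seq_along(cohort$records)) {
      rec <- cohort$records[[i]]
      base <- file.path(out_dir, sprintf("%s_ses%d", rec$subject_id, rec$session))
      paths[i] <- write_signal(rec$signal, base, format = format)
      utils::write.table(rec$truth_events, paste0(base, "_truth.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
    cohort$manifest$path <- paths
    utils::write.table(cohort$manifest, file.path(out_dir, "manifest.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(scores, file.path(out_dir, "clinical_scores.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    cfg <- config
    cfg$seed <- seed
    yaml::write_yaml(cfg, file.path(out_dir, "config.yaml"))
  }
  cohort
}

#' Write a signal to disk
#'
#' @param ts A [time_series].
#' @param base Path without extension.
#' @param format `"bin"` (raw little-endian float64, with a `.yaml` sidecar
#'   recording fs and n_samples) or `"txt"` (single-column text).
#' @return The signal file path.
#' @export
write_signal <- function(ts, base, format = c("bin", "txt")) {
  format <- match.arg(format)
  if (format == "bin") {
    path <- paste0(base, ".f64")
    con <- file(path, "wb")
    writeBin(ts$samples, con, size = 8, endian = "little")
    close(con)
    yaml::write_yaml(list(fs = ts$fs, n_samples = length(ts$samples),
                          t0 = ts$t0, dtype = "float64-le"),
                     paste0(base, ".yaml"))
  } else {
    path <- paste0(base, ".txt")
    utils::write.table(ts$samples, path, row.names = FALSE, col.names = FALSE)
  }
  path
}

#' Read a signal from disk
#'
#' Counterpart of [write_signal()]: raw float64 with YAML sidecar, or
#' single-column text (fs then taken from the `fs` argument).
#'
#' @param path Signal file path.
#' @param fs Sampling rate for text files without a sidecar.
#' @return A [time_series].
#' @export
read_signal <- function(path, fs = 1000) {
  if (grepl("\\.f64$", path)) {
    side <- yaml::read_yaml(sub("\\.f64$", ".yaml", path))
    con <- file(path, "rb")
    x <- readBin(con, "double", n = side$n_samples, size = 8, endian = "little")
    close(con)
    time_series(x, fs = side$fs, t0 = if (is.null(side$t0)) 0 else side$t0)
  } else {
    time_series(scan(path, quiet = TRUE), fs = fs)
  }
}

#' Load a cohort from a manifest written by [run_simulate()]
#'
#' @param manifest_path Path to `manifest.tsv`.
#' @return A `cohort` with signals loaded.
#' @export
read_cohort <- function(manifest_path) {
  man <- utils::read.delim(manifest_path)
  records <- lapply(seq_len(nrow(man)), function(i) {
    p <- man$path[i]
    if (!file.exists(p) && !grepl("^/", p))
      p <- file.path(dirname(manifest_path), basename(p))
    structure(list(subject_id = man$subject[i], group = man$group[i],
                   session = man$session[i], signal = read_signal(p),
                   truth_events = NULL, truth_rate = man$truth_rate[i]),
              class = "synthetic_subject")
  })
  sc_path <- file.path(dirname(manifest_path), "clinical_scores.tsv")
  structure(list(manifest = man, records = records,
                 clinical_scores = if (file.exists(sc_path))
                   utils::read.delim(sc_path) else NULL),
            class = "cohort")
}

#' Run the full burst analysis on a cohort
#'
#' The complete pipeline after simulation: beta filter + Hilbert envelope
#' per record, data-driven threshold selection across all records, burst
#' detection and feature summaries at the selected threshold, spectral
#' features, group models for the burst rate and per-event features,
#' symptom regressions (when clinical scores are present), the ROC suite,
#' and optionally the threshold sweep.
#'
#' @param cohort A `cohort`.
#' @param config Configuration list.
#' @param sweep Run the across-threshold robustness analysis (default
#'   FALSE; it refits the rate model at every grid point).
#' @param out_dir Optional directory to write all result tables as TSV.
#' @return A list of class `burst_analysis` with elements `threshold`
#'   (`threshold_grid`), `burst_summaries`, `events`, `spectral`,
#'   `rate_model`, `feature_models`, `symptom_effects`, `roc`, `sweep`.
#' @export
run_analyze <- function(cohort, config = default_config(), sweep = FALSE,
                        out_dir = NULL) {
  records <- cohort$records
  if (!length(records)) stop("empty cohort")
  envs <- cohort_envelopes(records, config)
  k_grid <- seq(config$threshold$k_min, config$threshold$k_max,
                by = config$threshold$k_step)
  thr <- optimize_threshold(envs, k_grid,
                            segment_len_s = config$threshold$segment_len_s,
                            center = config$threshold$center,
                            mode = config$threshold$mode)
  det <- detect_cohort(records, thr$k_star, config, envelopes = envs)
  spec_tab <- spectral_cohort(records, config)
  st <- det$summary_table
  rate_model <- if (length(unique(st$subject)) >= 4) fit_rate_model(st) else NULL
  feature_models <- NULL
  if (!is.null(det$events) && nrow(det$events) > 10 &&
      length(unique(st$group)) >= 2 && length(unique(st$session)) >= 2) {
    ev <- det$events
    mk <- function(col, fam) {
      d <- data.frame(value = ev[[col]], subject = ev$subject,
                      group = ev$group, session = ev$session)
      d <- d[d$value > 0, ]
      fit_feature_model(d, family = fam)
    }
    ibi <- do.call(rbind, lapply(seq_along(det$summaries), function(i) {
      su <- det$summaries[[i]]
      if (!length(su$ibis_ms)) return(NULL)
      data.frame(value = su$ibis_ms, subject = su$subject,
                 group = su$group, session = su$session)
    }))
    feature_models <- list(
      duration = mk("duration_s", "shifted_lognormal"),
      peak_amplitude = mk("peak_amp", "shifted_lognormal"),
      inter_burst_interval = fit_feature_model(ibi[ibi$value > 0, ],
                                               family = "lognormal"))
  }
  symptom_effects <- NULL
  if (!is.null(cohort$clinical_scores)) {
    pat <- st[st$group == "patient", ]
    if (nrow(pat)) symptom_effects <- fit_symptom_models(pat, cohort$clinical_scores)
  }
  roc <- if (length(unique(st$group)) >= 2) roc_suite(st, spec_tab) else NULL
  sweep_tab <- if (isTRUE(sweep))
    threshold_sweep(records, k_grid, config, envelopes = envs) else NULL
  res <- structure(list(threshold = thr, burst_summaries = st,
                        events = det$events, spectral = spec_tab,
                        rate_model = rate_model,
                        feature_models = feature_models,
                        symptom_effects = symptom_effects,
                        roc = roc, sweep = sweep_tab),
                   class = "burst_analysis")
  if (!is.null(out_dir)) write_analysis(res, out_dir)
  res
}

#' Write all tables of an analysis to TSV files
#'
#' @param res A `burst_analysis`.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the vector of files written.
#' @export
write_analysis <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  wt <- function(df, name) {
    if (is.null(df)) return()
    p <- file.path(out_dir, name)
    utils::write.table(df, p, sep = "\t", row.names = FALSE, quote = FALSE)
    written <<- c(written, p)
  }
  wt(data.frame(k = res$threshold$k_values, mean_r = res$threshold$mean_r),
     "threshold_grid.tsv")
  wt(res$burst_summaries, "burst_summaries.tsv")
  wt(res$events, "burst_events.tsv")
  wt(res$spectral, "spectral_features.tsv")
  if (!is.null(res$rate_model)) {
    wt(res$rate_model$contrasts, "rate_model_contrasts.tsv")
    wt(data.frame(term = c("group", "session", "interaction"),
                  bf = c(res$rate_model$bf_group, res$rate_model$bf_session,
                         res$rate_model$bf_interaction)), "rate_model_bf.tsv")
  }
  wt(res$symptom_effects, "symptom_effects.tsv")
  wt(res$roc, "roc_table.tsv")
  wt(res$sweep, "threshold_sweep.tsv")
  invisible(written)
}

#' @export
print.burst_analysis <- function(x, ...) {
  cat("<burst_analysis>\n")
  print(x$threshold)
  st <- x$burst_summaries
  for (g in unique(st$group)) {
    for (s in sort(unique(st$session))) {
      d <- st[st$group == g & st$session == s, ]
      if (!nrow(d)) next
      cat(sprintf("  %s session %d: rate %.1f/min (SD %.1f), median duration %.0f ms\n",
                  g, s, mean(d$rate_per_min), stats::sd(d$rate_per_min),
                  stats::median(d$median_duration_ms)))
    }
  }
  if (!is.null(x$rate_model)) print(x$rate_model)
  invisible(x)
}
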