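#' Cohort validation configuration
#'
#' Describes a synthetic cohort and which analyses to run over it. Each
#' subject follows the standard protocol (9 trials per day: 3 blocks x 3
#' trials) on the days listed for them.
#'
#' @param n_subjects Number of subjects (ignored if `subjects` given).
#' @param subjects Optional list of per-subject specs: each a list with
#'   `subject` (id number), optional `days` (default `1:2`) and optional
#'   generator overrides (any [trial_config()] field, e.g. `stride_time_H`).
#' @param trial Baseline [trial_config()] shared by the cohort.
#' @param analyses Character subset of `c("crp", "lle", "hurst")`.
#' @param crp_segments Segment pairs for the CRP analysis.
#' @param lle_roles Channel roles for the Lyapunov analysis.
#' @param seed Master seed; per-trial substreams are derived from it.
#' @return A `validation_config` list.
#' @export
validation_config <- function(n_subjects = 3, subjects = NULL,
                              trial = trial_config(),
                              analyses = c("crp", "lle", "hurst"),
                              crp_segments = "thigh",
                              lle_roles = "right_thigh_pitch",
                              seed = 1L) {
  if (is.null(subjects)) {
    subjects <- lapply(seq_len(n_subjects), function(s) list(subject = s))
  }
  structure(list(subjects = subjects, trial = trial,
                 analyses = match.arg(analyses, several.ok = TRUE),
                 crp_segments = crp_segments, lle_roles = lle_roles,
                 seed = as.integer(seed)),
            class = "validation_config")
}

#' Run the generate -> extract -> validate pipeline over a synthetic cohort
#'
#' For every trial of every subject/day: simulates the trial, detects gait
#' events, computes the spatiotemporal table, and runs the requested
#' analyses (continuous relative phase per segment pair, Wolf largest
#' Lyapunov exponent per channel role, Bayesian Hurst exponent of the
#' stride series plus shuffled surrogate). Deterministic given the config
#' seed. Subjects present on only one day are processed without failure.
#'
#' @param config A [validation_config()].
#' @param out_dir Optional directory; if given, per-trial and per
#'   subject/day summary CSVs and a run log of all parameter choices are
#'   written there.
#' @return A `validation_report`: `per_trial` (one row per trial x metric),
#'   `per_subject_day` (means over the trials present), `config`, `log`.
#' @export
run_validation <- function(config = validation_config(), out_dir = NULL) {
  if (!length(config$subjects)) gd_stop("empty cohort", "gaitdyn_domain_error")
  rows <- list()
  skipped <- character(0)
  for (sub in config$subjects) {
    days <- if (is.null(sub$days)) 1:2 else sub$days
    over <- sub[setdiff(names(sub), c("subject", "days"))]
    cfg <- modifyList(config$trial, over)
    for (key in subject_trial_keys(sub$subject, days = days)) {
      cfg$seed <- derive_seed(config$seed, sub$subject, key$day, key$block,
                              key$trial)
      res <- tryCatch(
        analyze_one_trial(cfg, key, config),
        error = function(e) {
          skipped <<- c(skipped, paste0(format(key), ": ", conditionMessage(e)))
          NULL
        })
      if (!is.null(res)) rows[[length(rows) + 1]] <- res
    }
  }
  if (!length(rows)) gd_stop("no trials analyzed", "gaitdyn_insufficient_data")
  per_trial <- do.call(rbind, rows)

  agg <- stats::aggregate(value ~ subject + day + metric, per_trial, mean)
  cnt <- stats::aggregate(value ~ subject + day + metric, per_trial, length)
  names(agg)[names(agg) == "value"] <- "mean"
  agg$n_trials <- cnt$value
  report <- structure(list(per_trial = per_trial, per_subject_day = agg,
                           config = config, skipped = skipped),
                      class = "validation_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    data.table::fwrite(format_csv_num(per_trial),
                       file.path(out_dir, "per_trial.csv"))
    data.table::fwrite(format_csv_num(agg),
                       file.path(out_dir, "per_subject_day.csv"))
    writeLines(run_log_lines(config, skipped), file.path(out_dir, "run_log.txt"))
  }
  report
}

# 6-significant-digit formatting for byte-stable summary files
format_csv_num <- function(df) {
  for (cn in names(df)) if (is.numeric(df[[cn]])) df[[cn]] <- signif(df[[cn]], 6)
  df
}

run_log_lines <- function(config, skipped) {
  cfg <- config$trial
  c(sprintf("gaitdyn %s", as.character(utils::packageVersion("gaitdyn"))),
    sprintf("seed: %d", config$seed),
    sprintf("analyses: %s", paste(config$analyses, collapse = ", ")),
    sprintf("crp_segments: %s", paste(config$crp_segments, collapse = ", ")),
    sprintf("lle_roles: %s", paste(config$lle_roles, collapse = ", ")),
    "generator parameters:",
    paste0("  ", names(cfg), " = ",
           vapply(cfg, function(v) paste(format(v), collapse = ","), "")),
    if (length(skipped)) c("skipped trials:", paste0("  ", skipped)) else
      "skipped trials: none")
}

analyze_one_trial <- function(cfg, key, config) {
  sim <- simulate_trial(cfg, key = key)
  trial <- sim$trial
  events <- detect_gait_events(trial)
  out <- list()
  add <- function(metric, value) {
    out[[length(out) + 1]] <<- data.frame(
      subject = key$subject, day = key$day, block = key$block,
      trial = key$trial, token = format(key), metric = metric, value = value)
  }
  if ("crp" %in% config$analyses) {
    for (seg in config$crp_segments) {
      cr <- trial_crp(trial, seg, events = events)
      add(paste0("crp_phi_mean_", seg), cr$phi_mean)
      add(paste0("crp_phi_sd_", seg), cr$phi_sd)
      add(paste0("crp_anomalous_", seg), as.numeric(cr$anomalous))
    }
  }
  if ("lle" %in% config$analyses) {
    for (role in config$lle_roles) {
      ll <- trial_lle(trial, role)
      add(paste0("lle_", role), ll$lambda1)
    }
  }
  if ("hurst" %in% config$analyses) {
    tab <- compute_gait_parameters(events, trial)
    hs <- stride_series_hurst(tab, sides = "right",
                              surrogate_seed = derive_seed(cfg$seed, 999))
    for (i in seq_len(nrow(hs))) {
      vn <- gsub(" ", "_", hs$variable[i])
      add(paste0("hurst_", vn), hs$H_hat[i])
      add(paste0("hurst_", vn, "_shuffled"), hs$H_shuffled[i])
    }
  }
  do.call(rbind, out)
}

#' Between-day test-retest consistency of cohort metrics
#'
#' For each subject with both days and each metric: the absolute difference
#' of day means; across the cohort, the ratio of between-subject variance
#' (of subject-level means) to within-subject variance (between-day
#' differences), reported descriptively. A ratio well above 1 indicates
#' that subjects are more distinguishable from each other than from their
#' own retest — the fingerprint-like consistency the metrics should show.
#'
#' @param report A `validation_report` from [run_validation()].
#' @return List: `per_subject` (subject x metric, `day1_mean`, `day2_mean`,
#'   `abs_diff`), `variance_ratio` (per metric; `NA` when fewer than two
#'   two-day subjects).
#' @export
consistency_summary <- function(report) {
  agg <- report$per_subject_day
  metrics <- unique(agg$metric)
  per_subject <- list()
  vr <- setNames(rep(NA_real_, length(metrics)), metrics)
  any_two_day <- FALSE
  for (m in metrics) {
    a <- agg[agg$metric == m, ]
    subs <- unique(a$subject)
    d1 <- setNames(rep(NA_real_, length(subs)), subs)
    d2 <- d1
    for (s in subs) {
      r1 <- a[a$subject == s & a$day == 1, "mean"]
      r2 <- a[a$subject == s & a$day == 2, "mean"]
      if (length(r1)) d1[as.character(s)] <- r1
      if (length(r2)) d2[as.character(s)] <- r2
    }
    both <- !is.na(d1) & !is.na(d2)
    if (any(both)) any_two_day <- TRUE
    per_subject[[m]] <- data.frame(
      metric = m, subject = subs, day1_mean = unname(d1), day2_mean = unname(d2),
      abs_diff = unname(abs(d1 - d2)))
    if (sum(both) >= 2) {
      subj_means <- (d1[both] + d2[both]) / 2
      between <- var(subj_means)
      within <- mean((d1[both] - d2[both])^2) / 2
      vr[m] <- if (within > 0) between / within else Inf
    }
  }
  if (!any_two_day) {
    gd_stop("no subject has both days; consistency undefined",
            "gaitdyn_insufficient_data")
  }
  list(per_subject = do.call(rbind, per_subject), variance_ratio = vr)
}
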