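#' Daily feature table for one participant
#'
#' Runs all four feature extractors over a validated sensor bundle and joins
#' them into one row per local study day: four mobility features, four call
#' features, two screen features and the nighttime-light sleep proxy. Days
#' without data in a stream carry `NA` (mobility) or zeros (event counts on
#' days the stream was active), and every study-window day appears exactly
#' once.
#'
#' @param bundle A `sensor_bundle`.
#' @param thresholds Named list overriding extraction constants:
#'   `displacement_m` (20), `cluster_radius_m` (150), `min_dwell_s` (120),
#'   `night_start_h` (23), `night_end_h` (7), `low_lux` (10),
#'   `high_lux` (1000).
#' @return Tibble with `participant_id`, `date` and the feature columns of
#'   [feature_domains] (plus supporting columns `hours_observed`,
#'   `n_missed`, `time_low_lux_min`, `time_high_lux_min`).
#' @export
extract_features <- function(bundle, thresholds = list()) {
  th <- list(displacement_m = 20, cluster_radius_m = 150, min_dwell_s = 120,
             night_start_h = 23, night_end_h = 7, low_lux = 10, high_lux = 1000)
  th[names(thresholds)] <- thresholds
  off <- bundle$meta[["tz_offset_min"]] %||% 0
  window_dates <- local_date(bundle$window[["start"]], off) +
    seq_len(round(diff(as.numeric(bundle$window)) / SECS_DAY)) - 1
  mob <- extract_mobility(bundle$gps, tz_offset_min = off,
                          radius_m = th$cluster_radius_m,
                          min_dwell_s = th$min_dwell_s,
                          displacement_m = th$displacement_m)
  cal <- extract_calls(bundle$calls, tz_offset_min = off)
  scr <- extract_screen(bundle$screen, tz_offset_min = off)
  lig <- extract_light(bundle$light, tz_offset_min = off,
                       night_start_h = th$night_start_h,
                       night_end_h = th$night_end_h,
                       low_lux = th$low_lux, high_lux = th$high_lux)
  take <- function(tbl, col) tbl[[col]][match(window_dates, tbl$date)]
  out <- fast_tibble(
    participant_id = rep(bundle$meta$participant_id, length(window_dates)),
    date = window_dates,
    time_sedentary_h = take(mob, "time_sedentary_h"),
    time_moving_h = take(mob, "time_moving_h"),
    distance_km = take(mob, "distance_km"),
    entropy_norm = take(mob, "entropy_norm"),
    hours_observed = take(mob, "hours_observed"),
    n_incoming = take(cal, "n_incoming"),
    n_outgoing = take(cal, "n_outgoing"),
    n_connected = take(cal, "n_connected"),
    n_missed = take(cal, "n_missed"),
    call_duration_min = take(cal, "call_duration_min"),
    n_unlocks = take(scr, "n_unlocks"),
    screen_time_min = take(scr, "screen_time_min"),
    mean_night_lux = take(lig, "mean_night_lux"),
    time_low_lux_min = take(lig, "time_low_lux_min"),
    time_high_lux_min = take(lig, "time_high_lux_min"))
  # a day with no events in an active event stream is a true zero, not missing
  cal_cols <- c("n_incoming", "n_outgoing", "n_connected", "n_missed",
                "call_duration_min")
  scr_cols <- c("n_unlocks", "screen_time_min")
  if (nrow(bundle$calls) > 0) {
    out[cal_cols] <- lapply(out[cal_cols], function(x) dplyr::coalesce(x, 0))
  }
  if (nrow(bundle$screen) > 0) {
    out[scr_cols] <- lapply(out[scr_cols], function(x) dplyr::coalesce(x, 0))
  }
  out
}

#' Pipeline configuration
#'
#' Collects every constant of the analysis in one auditable place: the
#' extraction thresholds (displacement radius, cluster radius, minimum dwell,
#' night window, lux thresholds), the retention requirement, the covariate
#' set, the outlier rule and the analysis options.
#'
#' @param input Either a [sim_config()] (the study is generated in memory) or
#'   a directory written by [write_simulated_study()] / laid out in the same
#'   schemas.
#' @param thresholds Extraction threshold overrides (see
#'   [extract_features()]).
#' @param required_days Minimum days of data for retention (default 14).
#' @param covariates Covariate columns for adjustment.
#' @param adjust_comorbidity Adjust each outcome for the other instruments'
#'   totals (default TRUE).
#' @param outlier_fence_k Tukey fence multiplier for extreme-outlier
#'   exclusion (default 3); `NULL` disables.
#' @param out_dir Optional output directory for tables, report and manifest.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input = sim_config(), thresholds = list(),
                            required_days = 14,
                            covariates = c("age", "sex", "maternal_education",
                                           "os", "assessment_month"),
                            adjust_comorbidity = TRUE, outlier_fence_k = 3,
                            out_dir = NULL) {
  structure(list(input = input, thresholds = thresholds,
                 required_days = required_days, covariates = covariates,
                 adjust_comorbidity = adjust_comorbidity,
                 outlier_fence_k = outlier_fence_k, out_dir = out_dir),
            class = "pipeline_config")
}

read_study_dir <- function(dir) {
  meta <- read_participant_meta(file.path(dir, "meta.csv"))
  ledger <- readr::read_csv(file.path(dir, "ledger.csv"), show_col_types = FALSE,
                            progress = FALSE)
  surveys <- readr::read_csv(file.path(dir, "surveys.csv"), show_col_types = FALSE,
                             progress = FALSE)
  bundles <- lapply(seq_len(nrow(meta)), function(i) {
    id <- meta$participant_id[i]
    pd <- file.path(dir, id)
    paths <- lapply(setNames(nm = names(stream_schemas)),
                    function(s) {
                      p <- file.path(pd, paste0(s, ".csv"))
                      if (file.exists(p)) p else NULL
                    })
    read_sensor_bundle(paths, meta[i, ])
  })
  names(bundles) <- meta$participant_id
  list(meta = meta, ledger = ledger, surveys = surveys, bundles = bundles)
}

#' Run the full analysis pipeline
#'
#' Orchestrates the stages: obtain the study (generate from a [sim_config()]
#' or read a study directory), apply the retention filters, extract daily
#' features for retained participants, score the surveys, average features to
#' participant level, run the adjusted-Spearman association analysis with
#' domain-specific outlier exclusion, the nested-model F comparisons, and the
#' discriminant-validity correlations. With `out_dir` set in the config, all
#' tables, a Markdown report and a manifest (config hash, seed, counts) are
#' written.
#'
#' @param config A [pipeline_config()].
#' @return A `digiphen_run` list: `retention`, `daily`, `scores`,
#'   `feature_matrix`, `associations`, `model_comparison`, `discriminant`,
#'   `descriptives`, `truth` (when simulated), `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  study <- if (inherits(config$input, "sim_config")) {
    simulate_study(config$input)
  } else if (is.character(config$input)) {
    read_study_dir(config$input)
  } else {
    stop_bad_arg("config$input must be a sim_config or a study directory")
  }
  retention <- apply_retention_filters(study$ledger, config$required_days)
  ids <- retained_ids(retention)
  if (length(ids) == 0) {
    manifest <- list(
      package_version = as.character(utils::packageVersion("digiphen")),
      config_hash = rlang::hash(config), seed = NA,
      n_enrolled = nrow(study$ledger), n_retained = 0L,
      exclusions = as.list(attr(retention, "exclusions")),
      outlier_exclusions = list())
    run <- structure(list(retention = retention, daily = tibble::tibble(),
                          scores = tibble::tibble(),
                          feature_matrix = tibble::tibble(),
                          associations = tibble::tibble(),
                          model_comparison = tibble::tibble(),
                          discriminant = tibble::tibble(),
                          descriptives = tibble::tibble(),
                          truth = study$truth, manifest = manifest),
                     class = "digiphen_run")
    if (!is.null(config$out_dir)) {
      dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
      write_report(run, file.path(config$out_dir, "report.md"))
    }
    return(run)
  }
  daily <- purrr::map_dfr(ids, function(id) {
    b <- study$bundles[[id]]
    if (is.null(b)) stop_bad_arg("stage features: no sensor bundle for %s", id)
    extract_features(b, config$thresholds)
  })
  scores <- score_surveys(study$surveys)
  fm <- participant_averages(daily) |>
    dplyr::inner_join(scores, by = "participant_id") |>
    dplyr::inner_join(study$meta, by = "participant_id")
  assoc <- associate_features(
    fm, covariates = config$covariates,
    adjust_comorbidity = config$adjust_comorbidity,
    outlier_fence_k = config$outlier_fence_k)
  feats <- intersect(names(feature_domains), names(fm))
  # n_connected is the identity n_incoming + n_outgoing under the adopted
  # connected-call definition, so it cannot enter the linear model alongside
  # them; it stays in the correlation analysis
  feats_model <- setdiff(feats, "n_connected")
  base_cov <- config$covariates
  mc <- purrr::map_dfr(c("scared_total", "cesdc_total"), function(oc) {
    fit <- nested_model_test(fm, oc, base_cov, feats_model)
    tibble::tibble(outcome = oc, F = fit$F, df1 = fit$df1, df2 = fit$df2,
                   p = fit$p, n = fit$n, r2_base = fit$r2_base,
                   r2_full = fit$r2_full)
  })
  disc <- discriminant_validity(fm, base = base_cov, features = feats_model)
  desc <- report_descriptives(fm)
  manifest <- list(
    package_version = as.character(utils::packageVersion("digiphen")),
    config_hash = rlang::hash(config),
    seed = if (inherits(config$input, "sim_config")) config$input$seed else NA,
    n_enrolled = nrow(study$ledger), n_retained = length(ids),
    exclusions = as.list(attr(retention, "exclusions")),
    outlier_exclusions = lapply(attr(assoc, "excluded") %||% list(), length))
  run <- structure(list(retention = retention, daily = daily, scores = scores,
                        feature_matrix = fm, associations = assoc,
                        model_comparison = mc, discriminant = disc,
                        descriptives = desc, truth = study$truth,
                        manifest = manifest),
                   class = "digiphen_run")
  if (!is.null(config$out_dir)) write_run(run, config$out_dir)
  run
}

#' @export
print.digiphen_run <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("<digiphen_run> %d enrolled -> %d retained (withdrew %d, short %d, missing sensors %d)\n",
              m$n_enrolled, m$n_retained, m$exclusions$withdrew,
              m$exclusions$insufficient_days, m$exclusions$missing_sensors))
  if (nrow(x$associations) > 0) {
    sig <- dplyr::filter(x$associations, .data$p < 0.05)
    cat(sprintf("  associations: %d feature x outcome pairs, %d with p < 0.05\n",
                nrow(x$associations), nrow(sig)))
  }
  for (i in seq_len(nrow(x$model_comparison))) {
    r <- x$model_comparison[i, ]
    cat(sprintf("  %s: F(%d, %d) = %.3f, p = %.4g\n", r$outcome, r$df1, r$df2,
                r$F, r$p))
  }
  invisible(x)
}

#' Descriptive statistics of participant-level features
#'
#' Mean and SD of each behavioral feature and instrument total across
#' participants — the descriptive table a sensing-study report opens with.
#'
#' @param fm Participant-level feature matrix (from the pipeline or
#'   [participant_averages()] joined with scores).
#' @return Tibble: `feature`, `domain`, `mean`, `sd`, `n`.
#' @export
report_descriptives <- function(fm) {
  feats <- c(intersect(names(feature_domains), names(fm)),
             intersect(c("scared_total", "cesdc_total", "asrs_total"),
                       names(fm)))
  purrr::map_dfr(feats, function(f) {
    v <- fm[[f]]
    tibble::tibble(feature = f,
                   domain = unname(feature_domains[f]) %||% "clinical",
                   mean = mean(v, na.rm = TRUE), sd = sd(v, na.rm = TRUE),
                   n = sum(!is.na(v)))
  }) |>
    dplyr::mutate(domain = dplyr::coalesce(.data$domain, "clinical"))
}

write_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(run$daily, file.path(dir, "features_daily.csv"), progress = FALSE)
  readr::write_csv(run$feature_matrix, file.path(dir, "feature_matrix.csv"),
                   progress = FALSE)
  readr::write_csv(run$associations, file.path(dir, "associations.csv"),
                   progress = FALSE)
  readr::write_csv(run$model_comparison, file.path(dir, "model_comparison.csv"),
                   progress = FALSE)
  readr::write_csv(run$discriminant, file.path(dir, "discriminant.csv"),
                   progress = FALSE)
  readr::write_csv(run$descriptives, file.path(dir, "descriptives.csv"),
                   progress = FALSE)
  jsonlite::write_json(run$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  write_report(run, file.path(dir, "report.md"))
  invisible(dir)
}

#' Write a human-readable Markdown report of a pipeline run
#'
#' Sections: retention flow (enrolled, per-reason exclusions, retained),
#' feature descriptives (mean, SD per feature), the association table per
#' outcome, the nested-model comparison, and the discriminant-validity
#' correlations. An empty cohort produces a report with an explicit
#' empty-state notice.
#'
#' @param run A `digiphen_run`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_report <- function(run, path) {
  m <- run$manifest
  fmt_tbl <- function(df) {
    df <- dplyr::mutate(df, dplyr::across(dplyr::where(is.numeric),
                                          ~ signif(.x, 4)))
    header <- paste("|", paste(names(df), collapse = " | "), "|")
    sep <- paste("|", paste(rep("---", ncol(df)), collapse = " | "), "|")
    body <- apply(df, 1, function(r) paste("|", paste(r, collapse = " | "), "|"))
    c(header, sep, body)
  }
  lines <- c(
    "# Passive-sensing analysis report", "",
    sprintf("Config hash: `%s`; package version %s.", m$config_hash,
            m$package_version), "",
    "## Retention flow", "",
    sprintf("- Enrolled: %d", m$n_enrolled),
    sprintf("- Withdrew: %d", m$exclusions$withdrew),
    sprintf("- Insufficient days: %d", m$exclusions$insufficient_days),
    sprintf("- Missing required sensors: %d", m$exclusions$missing_sensors),
    sprintf("- Retained: %d", m$n_retained), "")
  if (m$n_retained == 0) {
    lines <- c(lines, "**Empty cohort: no retained participants; no analyses run.**")
    writeLines(lines, path)
    return(invisible(path))
  }
  lines <- c(lines,
    "## Feature descriptives (participant-level means)", "",
    fmt_tbl(run$descriptives), "",
    "## Adjusted Spearman associations", "",
    fmt_tbl(run$associations), "",
    "## Nested model comparison", "",
    fmt_tbl(run$model_comparison), "",
    "## Discriminant validity of predicted scores", "",
    fmt_tbl(run$discriminant), "")
  writeLines(lines, path)
  invisible(path)
}
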