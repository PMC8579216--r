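# Delimited-text schemas for the four raw streams and study tables.
# Comma-delimited, header row required, ISO-8601 timestamps in UTC; unknown
# extra columns are ignored with a warning.

stream_schemas <- list(
  gps = c(timestamp = "T", lat = "d", lon = "d"),
  calls = c(timestamp = "T", direction = "c", duration_s = "d", contact_id = "c"),
  screen = c(timestamp = "T", state = "c"),
  light = c(timestamp = "T", lux = "d")
)

read_stream <- function(path, stream) {
  sch <- stream_schemas[[stream]]
  col_of <- function(tp) switch(tp, T = readr::col_datetime(),
                                d = readr::col_double(), c = readr::col_character())
  spec <- do.call(readr::cols, c(lapply(sch, col_of),
                                 list(.default = readr::col_guess())))
  df <- tryCatch(
    suppressWarnings( # parse problems surface as errors below, with location
      readr::read_csv(path, col_types = spec, progress = FALSE,
                      show_col_types = FALSE)),
    error = function(e) stop_bad_arg("parse error in %s: %s", path,
                                     conditionMessage(e)))
  prob <- readr::problems(df)
  if (nrow(prob) > 0) {
    stop_bad_arg("parse error in %s at line %d: expected %s, got '%s'", path,
                 prob$row[1] + 1, prob$expected[1], prob$actual[1])
  }
  missing <- setdiff(names(sch), names(df))
  if (length(missing)) {
    stop_bad_arg("%s: missing required column(s): %s", path,
                 paste(missing, collapse = ", "))
  }
  extra <- setdiff(names(df), names(sch))
  if (length(extra)) {
    warning(sprintf("%s: ignoring unknown column(s): %s", path,
                    paste(extra, collapse = ", ")), call. = FALSE)
  }
  df <- df[names(sch)]
  if ("timestamp" %in% names(df)) {
    if (anyNA(df$timestamp)) {
      stop_bad_arg("parse error in %s: unparseable timestamp at row %d", path,
                   which(is.na(df$timestamp))[1])
    }
    attr(df$timestamp, "tzone") <- "UTC"
  }
  tibble::as_tibble(df)
}

validate_stream <- function(df, stream, file = stream) {
  switch(stream,
    gps = {
      if (any(abs(df$lat) > 90) || any(abs(df$lon) > 180))
        stop_bad_arg("%s: coordinate out of bounds (|lat| <= 90, |lon| <= 180)", file)
      if (is.unsorted(as.numeric(df$timestamp), strictly = FALSE))
        stop_bad_arg("%s: timestamps must be nondecreasing", file)
    },
    calls = {
      bad <- setdiff(unique(df$direction), c("incoming", "outgoing", "missed"))
      if (length(bad))
        stop_bad_arg("%s: unknown call direction: %s", file, paste(bad, collapse = ", "))
      if (any(df$duration_s < 0))
        stop_bad_arg("%s: negative call duration", file)
      if (any(df$direction == "missed" & df$duration_s != 0))
        stop_bad_arg("%s: missed calls must have duration 0", file)
    },
    screen = {
      bad <- setdiff(unique(df$state), c("on", "off"))
      if (length(bad))
        stop_bad_arg("%s: unknown screen state: %s", file, paste(bad, collapse = ", "))
      if (is.unsorted(as.numeric(df$timestamp), strictly = FALSE))
        stop_bad_arg("%s: timestamps must be nondecreasing", file)
    },
    light = {
      if (any(df$lux < 0)) stop_bad_arg("%s: negative light intensity", file)
    })
  invisible(df)
}

#' Read and validate one participant's sensor bundle
#'
#' Reads the four raw stream files (GPS, calls, screen, light) from their CSV
#' schemas, validates each stream (coordinate bounds, direction/state enums,
#' time ordering, nonnegative durations and intensities), and drops rows
#' outside the participant's 14-day study window, recording the dropped count
#' per stream.
#'
#' File schemas (comma-delimited, header row, ISO-8601 UTC timestamps):
#' `gps.csv`: `timestamp,lat,lon`; `calls.csv`:
#' `timestamp,direction,duration_s,contact_id`; `screen.csv`:
#' `timestamp,state`; `light.csv`: `timestamp,lux`.
#'
#' @param paths Named list/vector with elements `gps`, `calls`, `screen`,
#'   `light` giving file paths. A missing element yields an empty stream.
#' @param meta One-row tibble of participant metadata (see
#'   [read_participant_meta()]); must include `participant_id`,
#'   `tz_offset_min`, and the study window start `study_start` (local date).
#' @param study_days Length of the study window in days (default 14).
#' @return A `sensor_bundle`: list with `meta`, `gps`, `calls`, `screen`,
#'   `light`, `window` (UTC start/end), and `dropped` (rows outside the
#'   window, per stream).
#' @export
read_sensor_bundle <- function(paths, meta, study_days = 14) {
  streams <- lapply(setNames(names(stream_schemas), names(stream_schemas)),
                    function(s) {
    p <- paths[[s]]
    if (is.null(p) || is.na(p)) {
      empty_stream(s)
    } else {
      if (!file.exists(p)) stop_bad_arg("file not found: %s", p)
      validate_stream(read_stream(p, s), s, file = p)
    }
  })
  new_sensor_bundle(meta, streams$gps, streams$calls, streams$screen,
                    streams$light, study_days = study_days)
}

empty_stream <- function(stream) {
  sch <- stream_schemas[[stream]]
  cols <- lapply(sch, function(tp) switch(tp, T = as_utc_posix(numeric(0)),
                                          d = double(0), c = character(0)))
  tibble::as_tibble(setNames(cols, names(sch)))
}

#' Construct a validated sensor bundle from in-memory streams
#'
#' The in-memory counterpart of [read_sensor_bundle()]; used by the synthetic
#' generator and anywhere streams are already tibbles. Validation and
#' study-window clipping are identical.
#'
#' @param meta One-row participant metadata tibble.
#' @param gps,calls,screen,light Stream tibbles in the schemas of
#'   [read_sensor_bundle()].
#' @param study_days Study window length in days (default 14).
#' @return A `sensor_bundle` object.
#' @export
new_sensor_bundle <- function(meta, gps, calls, screen, light, study_days = 14) {
  stopifnot(nrow(meta) == 1)
  for (s in names(stream_schemas)) {
    validate_stream(get(s), s)
  }
  off <- meta[["tz_offset_min"]] %||% 0
  w0 <- date_to_utc_midnight(as.Date(meta$study_start), off)
  w1 <- w0 + study_days * SECS_DAY
  clip <- function(df) {
    inside <- as.numeric(df$timestamp) >= w0 & as.numeric(df$timestamp) < w1
    list(df = df[inside, , drop = FALSE], dropped = sum(!inside))
  }
  g <- clip(gps); c_ <- clip(calls); s <- clip(screen); l <- clip(light)
  structure(list(
    meta = meta, gps = g$df, calls = c_$df, screen = s$df, light = l$df,
    window = c(start = as_utc_posix(w0), end = as_utc_posix(w1)),
    dropped = c(gps = g$dropped, calls = c_$dropped, screen = s$dropped,
                light = l$dropped)),
    class = "sensor_bundle")
}

#' @export
print.sensor_bundle <- function(x, ...) {
  cat(sprintf("<sensor_bundle> participant %s\n", x$meta$participant_id))
  cat(sprintf("  window: %s to %s (UTC)\n", format(x$window[["start"]]),
              format(x$window[["end"]])))
  cat(sprintf("  gps: %d fixes | calls: %d | screen: %d events | light: %d samples\n",
              nrow(x$gps), nrow(x$calls), nrow(x$screen), nrow(x$light)))
  if (sum(x$dropped) > 0)
    cat(sprintf("  dropped outside window: %s\n",
                paste(names(x$dropped), x$dropped, sep = "=", collapse = " ")))
  invisible(x)
}

#' Write a sensor bundle's streams to CSV files
#'
#' Inverse of [read_sensor_bundle()]: writes the four streams in their schema
#' column order so that a write-read cycle reproduces each stream
#' record-for-record.
#'
#' @param bundle A `sensor_bundle`.
#' @param dir Output directory (created if needed); files are named
#'   `gps.csv`, `calls.csv`, `screen.csv`, `light.csv`.
#' @return Invisibly, the named vector of written paths.
#' @export
write_sensor_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- setNames(file.path(dir, paste0(names(stream_schemas), ".csv")),
                    names(stream_schemas))
  for (s in names(stream_schemas)) {
    df <- bundle[[s]]
    if ("timestamp" %in% names(df)) {
      df$timestamp <- format(df$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
    }
    readr::write_csv(df, paths[[s]], progress = FALSE)
  }
  invisible(paths)
}

#' Read the participant metadata table
#'
#' One row per participant: `participant_id`, `age`, `sex`,
#' `maternal_education` (one of `below_hs`, `hs`, `further`, `university`,
#' `missing`), `os` (`ios`/`android`), `assessment_month`, lifetime-diagnosis
#' flags, `tz_offset_min` and `study_start`.
#'
#' @param path CSV path.
#' @return Tibble of participant metadata, validated.
#' @export
read_participant_meta <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_participant_meta(tibble::as_tibble(df))
}

validate_participant_meta <- function(meta) {
  req <- c("participant_id", "age", "sex", "maternal_education", "os",
           "assessment_month")
  missing <- setdiff(req, names(meta))
  if (length(missing))
    stop_bad_arg("meta: missing column(s): %s", paste(missing, collapse = ", "))
  if (any(meta$age < 10 | meta$age > 21))
    stop_bad_arg("meta: age outside the study range [10, 21]")
  lev <- c("below_hs", "hs", "further", "university", "missing")
  bad <- setdiff(unique(meta$maternal_education), lev)
  if (length(bad))
    stop_bad_arg("meta: unknown maternal_education level(s): %s",
                 paste(bad, collapse = ", "))
  if (!all(meta$os %in% c("ios", "android")))
    stop_bad_arg("meta: os must be 'ios' or 'android'")
  if (is.null(meta[["tz_offset_min"]])) meta$tz_offset_min <- 0
  meta
}

#' Apply the study's retention filters to a cohort ledger
#'
#' A participant is retained when enrolled, not withdrawn, providing at least
#' `required_days` days of data, and having all required sensors. Exclusions
#' are attributed uniquely, in reporting order: withdrawal first, then
#' insufficient days, then missing sensors — a participant failing several
#' filters counts once, under the first.
#'
#' @param ledger Tibble with `participant_id`, `withdrew` (logical),
#'   `days_provided`, `has_required_sensors` (logical); optionally `enrolled`
#'   (default `TRUE`).
#' @param required_days Minimum days of data (default 14).
#' @return Tibble with `participant_id`, `retained` and `exclusion_reason`
#'   (`NA` for retained; else `"withdrew"`, `"insufficient_days"`,
#'   `"missing_sensors"`). Per-reason counts are attached as attribute
#'   `"exclusions"`, and retained ids via `retained_ids()`.
#' @export
apply_retention_filters <- function(ledger, required_days = 14) {
  if (nrow(ledger) == 0) {
    out <- tibble::tibble(participant_id = character(0), retained = logical(0),
                          exclusion_reason = character(0))
    attr(out, "exclusions") <- c(withdrew = 0L, insufficient_days = 0L,
                                 missing_sensors = 0L)
    return(out)
  }
  enrolled <- ledger[["enrolled"]] %||% rep(TRUE, nrow(ledger))
  stopifnot(all(ledger$days_provided >= 0))
  reason <- dplyr::case_when(
    !enrolled ~ "not_enrolled",
    ledger$withdrew ~ "withdrew",
    ledger$days_provided < required_days ~ "insufficient_days",
    !ledger$has_required_sensors ~ "missing_sensors",
    TRUE ~ NA_character_)
  out <- tibble::tibble(participant_id = ledger$participant_id,
                        retained = is.na(reason) & enrolled,
                        exclusion_reason = reason)
  attr(out, "exclusions") <- c(
    withdrew = sum(reason == "withdrew", na.rm = TRUE),
    insufficient_days = sum(reason == "insufficient_days", na.rm = TRUE),
    missing_sensors = sum(reason == "missing_sensors", na.rm = TRUE))
  out
}

#' @rdname apply_retention_filters
#' @param retention Result of `apply_retention_filters()`.
#' @return `retained_ids()`: character vector of retained participant ids.
#' @export
retained_ids <- function(retention) {
  retention$participant_id[retention$retained]
}
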