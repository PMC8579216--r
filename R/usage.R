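#' Pair screen on/off events into sessions
#'
#' Transforms a raw stream of screen `on`/`off` events into use sessions.
#' Consecutive same-state events are deduplicated keeping the first; an `off`
#' before any `on` is dropped; a trailing unmatched `on` is closed at the next
#' local midnight; and sessions straddling local midnight are split at the
#' boundary so every session lies inside one local day. All repairs are
#' counted and attached as attribute `"repairs"`.
#'
#' @param screen Tibble with `timestamp` (POSIXct, UTC) and `state`
#'   (`"on"`/`"off"`), time-ordered.
#' @param tz_offset_min Participant's UTC offset in minutes.
#' @return Tibble of sessions: `date` (local), `start`, `end` (POSIXct UTC),
#'   `duration_s`, plus a `split` flag for midnight-split halves (so unlock
#'   counts can count each physical unlock once).
#' @export
pair_screen_sessions <- function(screen, tz_offset_min = 0) {
  empty <- tibble::tibble(date = as.Date(character(0)),
                          start = as_utc_posix(numeric(0)),
                          end = as_utc_posix(numeric(0)),
                          duration_s = double(0), split = logical(0))
  repairs <- c(dedup = 0L, leading_off = 0L, unmatched_on = 0L)
  if (nrow(screen) == 0) { attr(empty, "repairs") <- repairs; return(empty) }
  stopifnot(all(screen$state %in% c("on", "off")))
  t <- as.numeric(screen$timestamp)
  ord <- order(t)
  t <- t[ord]; state <- screen$state[ord]
  keep <- c(TRUE, state[-1] != state[-length(state)])
  repairs["dedup"] <- sum(!keep)
  t <- t[keep]; state <- state[keep]
  if (state[1] == "off") {
    repairs["leading_off"] <- 1L
    t <- t[-1]; state <- state[-1]
  }
  if (length(t) == 0) { attr(empty, "repairs") <- repairs; return(empty) }
  if (state[length(state)] == "on") {
    repairs["unmatched_on"] <- 1L
    last_on <- t[length(t)]
    midnight <- (floor(local_epoch(last_on, tz_offset_min) / SECS_DAY) + 1) *
      SECS_DAY - tz_offset_min * 60
    t <- c(t, midnight); state <- c(state, "off")
  }
  on_t <- t[state == "on"]; off_t <- t[state == "off"]
  stopifnot(length(on_t) == length(off_t))
  ok <- off_t > on_t
  on_t <- on_t[ok]; off_t <- off_t[ok]
  # split at every local midnight the session spans; a session ending exactly
  # at midnight belongs wholly to the earlier day (half-open days)
  d0 <- floor(local_epoch(on_t, tz_offset_min) / SECS_DAY)
  offl <- local_epoch(off_t, tz_offset_min)
  d1 <- floor(offl / SECS_DAY) - (offl %% SECS_DAY == 0)
  nseg <- pmax(d1 - d0, 0) + 1
  i <- rep(seq_along(on_t), nseg)
  seg <- sequence(nseg) - 1
  seg_day <- d0[i] + seg
  day_start_utc <- seg_day * SECS_DAY - tz_offset_min * 60
  s <- pmax(on_t[i], day_start_utc)
  e <- pmin(off_t[i], day_start_utc + SECS_DAY)
  out <- fast_tibble(
    date = as.Date(seg_day, origin = "1970-01-01"),
    start = as_utc_posix(s), end = as_utc_posix(e),
    duration_s = e - s, split = seg > 0)
  attr(out, "repairs") <- repairs
  out
}

#' Daily screen-use features
#'
#' Unlock count (number of use sessions starting that local day; halves of a
#' midnight-split session count once, on the day the session began) and total
#' screen time in minutes per local day.
#'
#' @inheritParams pair_screen_sessions
#' @return Tibble: `date`, `n_unlocks`, `screen_time_min`.
#' @export
extract_screen <- function(screen, tz_offset_min = 0) {
  sessions <- pair_screen_sessions(screen, tz_offset_min)
  if (nrow(sessions) == 0) {
    out <- tibble::tibble(date = as.Date(character(0)), n_unlocks = integer(0),
                          screen_time_min = double(0))
    attr(out, "repairs") <- attr(sessions, "repairs")
    return(out)
  }
  d <- as.numeric(sessions$date)
  agg <- rowsum(cbind(unlocks = as.numeric(!sessions$split),
                      mins = sessions$duration_s / 60), d)
  out <- fast_tibble(date = as.Date(as.numeric(rownames(agg)),
                                       origin = "1970-01-01"),
                        n_unlocks = as.integer(agg[, "unlocks"]),
                        screen_time_min = unname(agg[, "mins"]))
  attr(out, "repairs") <- attr(sessions, "repairs")
  out
}

#' Daily call features
#'
#' Counts and total duration of phone calls per local day. A call is
#' "connected" when its direction is incoming or outgoing and its duration is
#' positive; missed calls are counted separately and never contribute to the
#' incoming count or to call duration.
#'
#' @param calls Tibble with `timestamp` (POSIXct, UTC), `direction`
#'   (`"incoming"`/`"outgoing"`/`"missed"`), `duration_s`.
#' @param tz_offset_min Participant's UTC offset in minutes.
#' @return Tibble: `date`, `n_incoming`, `n_outgoing`, `n_connected`,
#'   `n_missed`, `call_duration_min`.
#' @export
extract_calls <- function(calls, tz_offset_min = 0) {
  if (nrow(calls) == 0) {
    return(tibble::tibble(date = as.Date(character(0)), n_incoming = integer(0),
                          n_outgoing = integer(0), n_connected = integer(0),
                          n_missed = integer(0), call_duration_min = double(0)))
  }
  stopifnot(all(calls$direction %in% c("incoming", "outgoing", "missed")),
            all(calls$duration_s >= 0))
  if (any(calls$direction == "missed" & calls$duration_s != 0)) {
    stop_bad_arg("missed calls must have duration 0")
  }
  d <- as.numeric(local_date(calls$timestamp, tz_offset_min))
  connected <- calls$direction %in% c("incoming", "outgoing") &
    calls$duration_s > 0
  agg <- rowsum(cbind(
    inc = as.numeric(calls$direction == "incoming" & connected),
    out = as.numeric(calls$direction == "outgoing" & connected),
    conn = as.numeric(connected),
    miss = as.numeric(calls$direction == "missed"),
    mins = ifelse(connected, calls$duration_s, 0) / 60), d)
  fast_tibble(date = as.Date(as.numeric(rownames(agg)), origin = "1970-01-01"),
                 n_incoming = as.integer(agg[, "inc"]),
                 n_outgoing = as.integer(agg[, "out"]),
                 n_connected = as.integer(agg[, "conn"]),
                 n_missed = as.integer(agg[, "miss"]),
                 call_duration_min = unname(agg[, "mins"]))
}

#' Nighttime ambient-light features (sleep proxy)
#'
#' Summarizes ambient light over the 11 PM-7 AM local night window, attributed
#' to the date containing 11 PM. Light streams log *changes* in intensity, so
#' each sample holds its value until the next one (zero-order hold); the most
#' recent sample before the window start is carried into the head of the
#' window. A night with no sample inside the window is reported missing.
#' Features: time-weighted mean lux over the covered window, and minutes spent
#' below `low_lux` (darkness) and above `high_lux` (bright light).
#'
#' @param light Tibble with `timestamp` (POSIXct, UTC) and `lux` (>= 0).
#' @param tz_offset_min Participant's UTC offset in minutes.
#' @param night_start_h,night_end_h Local clock hours bounding the night
#'   window (defaults 23 and 7, an 8-hour window).
#' @param low_lux,high_lux Thresholds for the darkness / bright-light ranges
#'   (defaults 10 and 1000 lux).
#' @return Tibble: `date` (night start date), `mean_night_lux`,
#'   `time_low_lux_min`, `time_high_lux_min`, `night_coverage_min`.
#' @export
extract_light <- function(light, tz_offset_min = 0, night_start_h = 23,
                          night_end_h = 7, low_lux = 10, high_lux = 1000) {
  stopifnot(low_lux < high_lux)
  empty <- tibble::tibble(date = as.Date(character(0)), mean_night_lux = double(0),
                          time_low_lux_min = double(0), time_high_lux_min = double(0),
                          night_coverage_min = double(0))
  if (nrow(light) == 0) return(empty)
  stopifnot(all(light$lux >= 0))
  le <- local_epoch(light$timestamp, tz_offset_min)
  ord <- order(le)
  le <- le[ord]; lux <- light$lux[ord]
  window_len <- ((night_end_h - night_start_h) %% 24) * 3600
  # candidate nights: any local date whose window could contain a sample
  days <- sort(unique(floor((le - night_start_h * 3600) / SECS_DAY)))
  nd <- length(days)
  meanv <- lowv <- highv <- cov <- rep(NA_real_, nd)
  for (j in seq_len(nd)) {
    w0 <- days[j] * SECS_DAY + night_start_h * 3600
    w1 <- w0 + window_len
    inside <- le >= w0 & le < w1
    if (!any(inside)) next
    st <- le[inside]; sv <- lux[inside]
    prior <- which(le < w0)
    if (length(prior) && st[1] > w0) {   # carry the held value into the window head
      st <- c(w0, st); sv <- c(lux[max(prior)], sv)
    }
    dur <- c(st[-1], w1) - st
    meanv[j] <- sum(sv * dur) / sum(dur)
    lowv[j] <- sum(dur[sv < low_lux]) / 60
    highv[j] <- sum(dur[sv > high_lux]) / 60
    cov[j] <- sum(dur) / 60
  }
  got <- !is.na(cov)
  if (!any(got)) return(empty)
  fast_tibble(date = as.Date(days[got], origin = "1970-01-01"),
                 mean_night_lux = meanv[got], time_low_lux_min = lowv[got],
                 time_high_lux_min = highv[got], night_coverage_min = cov[got])
}
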