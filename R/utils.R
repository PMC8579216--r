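# Time arithmetic. Timestamps are stored as POSIXct in UTC; each participant
# carries a fixed UTC offset (minutes) and every feature window (days, hours,
# the 11 PM-7 AM night window) is computed on the local clock.

SECS_DAY <- 86400

# epoch seconds on the local clock
local_epoch <- function(t, tz_offset_min = 0) {
  as.numeric(t) + tz_offset_min * 60
}

local_date <- function(t, tz_offset_min = 0) {
  as.Date(floor(local_epoch(t, tz_offset_min) / SECS_DAY), origin = "1970-01-01")
}

# seconds since local midnight, in [0, 86400)
local_sec_of_day <- function(t, tz_offset_min = 0) {
  local_epoch(t, tz_offset_min) %% SECS_DAY
}

# UTC instant of local midnight for a local date
date_to_utc_midnight <- function(date, tz_offset_min = 0) {
  as.numeric(date) * SECS_DAY - tz_offset_min * 60
}

as_utc_posix <- function(x) as.POSIXct(x, origin = "1970-01-01", tz = "UTC")

stop_bad_arg <- function(msg, ...) stop(sprintf(msg, ...), call. = FALSE)

# tibble() re-validates names and recycles via rlang quosures, which dominates
# runtime in the per-participant loops; this skips the checks for internally
# constructed, known-good column sets
fast_tibble <- function(...) {
  l <- list(...)
  tibble::new_tibble(l, nrow = length(l[[1]]))
}
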