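# shared fixture builders; everything is generated in code

utc <- function(s) as.POSIXct(s, origin = "1970-01-01", tz = "UTC")

# a GPS tibble from seconds-of-day and meter offsets around a reference point
gps_from_offsets <- function(sec, dx_m, dy_m, lat0 = 44.65, lon0 = -63.57,
                             day0 = as.Date("2020-03-02")) {
  m_per_deg <- pi * 6371000 / 180
  tibble::tibble(
    timestamp = utc(as.numeric(day0) * 86400 + sec),
    lat = lat0 + dy_m / m_per_deg,
    lon = lon0 + dx_m / (m_per_deg * cos(lat0 * pi / 180)))
}

screen_events <- function(sec, states, day0 = as.Date("2020-03-02")) {
  tibble::tibble(timestamp = utc(as.numeric(day0) * 86400 + sec),
                 state = states)
}

light_samples <- function(sec, lux, day0 = as.Date("2020-03-02")) {
  tibble::tibble(timestamp = utc(as.numeric(day0) * 86400 + sec), lux = lux)
}

call_events <- function(sec, direction, duration_s,
                        day0 = as.Date("2020-03-02")) {
  tibble::tibble(timestamp = utc(as.numeric(day0) * 86400 + sec),
                 direction = direction, duration_s = duration_s,
                 contact_id = paste0("c", seq_along(sec)))
}

meta_row <- function(id = "P0001", start = as.Date("2020-03-02"), tz = 0) {
  tibble::tibble(participant_id = id, age = 16, sex = "female",
                 maternal_education = "university", os = "ios",
                 assessment_month = 3, dx_depression = FALSE, dx_gad = FALSE,
                 dx_social_phobia = FALSE, tz_offset_min = tz,
                 study_start = start)
}

# small deterministic cohort for pipeline-level tests
small_config <- function(n = 40, seed = 3, ...) {
  sim_config(n_participants = n, seed = seed, ...)
}
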