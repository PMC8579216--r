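# Synthetic cohort generator. Emulates a 14-day passive-sensing study:
# anchor-based GPS trajectories passed through the 20 m displacement filter,
# event-based call and screen streams, a nighttime ambient-light step process,
# graded item-level survey responses, and a retention ledger. Couplings
# between latent symptom scores and behavior are planted with configurable
# standardized magnitudes so the analysis stack can be validated end to end.

M_PER_DEG <- pi * 6371000 / 180

# Deterministic per-(participant, day) substream seeds: changing the cohort
# size or day count never perturbs another participant-day's draws.
mix_seed <- function(seed, pid, day) {
  s <- abs(as.numeric(seed)) %% 1e6
  as.integer((s * 2654435 + pid * 97561 + day * 7919 + 12345) %% 2147483647)
}

#' Simulation configuration for a synthetic sensing cohort
#'
#' Defaults encode the emulated study's conditions: 161 enrolled participants
#' observed for 14 days; retention probabilities 11/161 (withdrawal), 25/161
#' (short data) and 3/161 (missing sensors); demographics drawn from the
#' cohort's printed proportions (age ~ Normal(18, 2.76) clipped to \[10, 21\],
#' 78.6% female, 78.6% iOS, five maternal-education levels); and planted
#' symptom-behavior couplings of standardized magnitude 0.3 with the
#' directions: depression increases sedentary time and nighttime light and
#' decreases distance/mobility and outgoing calls; anxiety decreases
#' sedentary time and increases distance/mobility and screen time. Latent
#' anxiety and depression correlate 0.5; ADHD symptoms are independent.
#'
#' @param n_participants Enrolled cohort size (default 161).
#' @param seed Master seed; all randomness derives from it via per
#'   participant-day substreams.
#' @param days Study window length in days (default 14).
#' @param effects Named list of standardized coupling magnitudes (see
#'   defaults in the function signature); set a value to 0 to null a
#'   coupling.
#' @param rates Named list of base behavioral rates (trips/day, anchor
#'   geometry, call/screen/light process parameters). Unnamed entries keep
#'   their defaults.
#' @param retention Probabilities for `withdraw`, `short_data`,
#'   `missing_sensor` (must sum to < 1); the remainder is retained.
#' @param latent_cor Correlation of latent anxiety and depression (default 0.5).
#' @param survey_loading Loading of instrument totals on their latent score
#'   (default 0.7).
#' @param malformed Inject stream malformations (duplicate events, unpaired
#'   screen-on, out-of-order rows) to exercise repair paths (default FALSE).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_participants = 161, seed = 1, days = 14,
                       effects = list(), rates = list(),
                       retention = c(withdraw = 11 / 161, short_data = 25 / 161,
                                     missing_sensor = 3 / 161),
                       latent_cor = 0.5, survey_loading = 0.7,
                       malformed = FALSE) {
  eff <- list(mobility_anxiety = 0.3, mobility_depression = -0.3,
              outgoing_depression = -0.3, screen_anxiety = 0.3,
              night_light_depression = 0.3)
  eff[names(effects)] <- effects
  rt <- list(
    trips_per_day = 2.5, away_budget_h = 3, away_budget_sdlog = 0.6,
    trip_speed_ms = 8, n_anchors = 5, anchor_dist_km = c(0.4, 2),
    home_lat = 44.65, home_lon = -63.57,
    incoming_per_day = 1.8, outgoing_per_day = 2.1, missed_per_day = 0.5,
    call_duration_meanlog_in = log(180), call_duration_meanlog_out = log(60),
    call_duration_sdlog = 1, call_duration_person_sdlog = 0.9,
    primary_anchor_weight = 0.75,
    screen_sessions_per_day = 54, screen_session_meanlog = log(210),
    screen_session_sdlog = 0.8,
    light_episodes_per_night = 1, episode_lux_meanlog = log(300),
    episode_lux_sdlog = 0.5, episode_dur_min = c(10, 30),
    baseline_lux = c(0.5, 5))
  rt[names(rates)] <- rates
  stopifnot(sum(retention) < 1, all(retention >= 0), days >= 1)
  structure(list(n_participants = n_participants, seed = seed, days = days,
                 effects = eff, rates = rt, retention = retention,
                 latent_cor = latent_cor, survey_loading = survey_loading,
                 malformed = malformed),
            class = "sim_config")
}

#' Simulate cohort demographics, latent profiles and retention ledger
#'
#' Draws, per enrolled participant: correlated latent anxiety/depression and
#' independent ADHD scores; demographics from the study's printed
#' distributions; a home location and a personal ring of trip anchors; and a
#' retention outcome drawn as one categorical event (withdraw, short data,
#' missing sensors, or retained) so exclusion reasons are disjoint by
#' construction.
#'
#' @param config A [sim_config()].
#' @return List with `meta` (participant metadata tibble), `profiles` (latent
#'   scores and personal generator parameters) and `ledger` (retention
#'   tibble).
#' @export
simulate_cohort <- function(config) {
  n <- config$n_participants
  rt <- config$rates
  rho <- config$latent_cor
  edu_lev <- c("below_hs", "hs", "further", "university", "missing")
  cat_p <- c(config$retention, retained = 1 - sum(config$retention))
  anx <- dep <- adhd <- age <- home_lat <- home_lon <- away <- blux <-
    call_mult <- numeric(n)
  sex <- edu <- os <- fate <- character(n)
  month <- days_provided <- integer(n)
  start <- numeric(n)
  dx_dep <- dx_gad <- dx_soc <- logical(n)
  adlat <- adlon <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(mix_seed(config$seed, i, 0L))
    z <- rnorm(3)
    anx[i] <- z[1]
    dep[i] <- rho * z[1] + sqrt(1 - rho^2) * z[2]
    adhd[i] <- z[3]
    # base location 18.23 compensates the [10, 21] clipping so the cohort
    # mean age lands on the study's 18.0
    age[i] <- min(max(rnorm(1, 18.23, 2.76), 10), 21)
    sex[i] <- sample(c("female", "male"), 1, prob = c(96, 26) / 122)
    edu[i] <- sample(edu_lev, 1, prob = c(5, 18, 29, 66, 4) / 122)
    os[i] <- sample(c("ios", "android"), 1, prob = c(96, 26) / 122)
    month[i] <- sample(2:7, 1)
    start[i] <- as.numeric(as.Date(sprintf("2020-%02d-01", month[i]))) +
      sample.int(28, 1) - 1
    k <- rt$n_anchors
    dist_m <- runif(k, rt$anchor_dist_km[1], rt$anchor_dist_km[2]) * 1000
    bearing <- runif(k, 0, 2 * pi)
    home_lat[i] <- rt$home_lat + rnorm(1, 0, 0.02)
    home_lon[i] <- rt$home_lon + rnorm(1, 0, 0.02)
    adlat[[i]] <- dist_m * cos(bearing) / M_PER_DEG
    adlon[[i]] <- dist_m * sin(bearing) / (M_PER_DEG * cos(home_lat[i] * pi / 180))
    away[i] <- rt$away_budget_h * 3600 * rlnorm(1, 0, rt$away_budget_sdlog)
    blux[i] <- runif(1, rt$baseline_lux[1], rt$baseline_lux[2])
    call_mult[i] <- rlnorm(1, 0, rt$call_duration_person_sdlog)
    dx_dep[i] <- runif(1) < 30 / 122
    dx_gad[i] <- runif(1) < 39 / 122
    dx_soc[i] <- runif(1) < 12 / 122
    fate[i] <- sample(names(cat_p), 1, prob = cat_p)
    days_provided[i] <- if (fate[i] %in% c("withdraw", "short_data")) {
      sample.int(config$days - 1, 1)
    } else config$days
  }
  ids <- sprintf("P%04d", seq_len(n))
  list(
    meta = tibble::tibble(
      participant_id = ids, age = age, sex = sex, maternal_education = edu,
      os = os, assessment_month = month, dx_depression = dx_dep,
      dx_gad = dx_gad, dx_social_phobia = dx_soc, tz_offset_min = 0,
      study_start = as.Date(start, origin = "1970-01-01")),
    profiles = tibble::tibble(
      participant_id = ids, pid = seq_len(n), latent_anxiety = anx,
      latent_depression = dep, latent_adhd = adhd, home_lat = home_lat,
      home_lon = home_lon, anchor_dlat = adlat, anchor_dlon = adlon,
      away_budget_s = away, baseline_lux = blux, call_dur_mult = call_mult),
    ledger = tibble::tibble(
      participant_id = ids, enrolled = TRUE, withdrew = fate == "withdraw",
      days_provided = days_provided,
      has_required_sensors = fate != "missing_sensor"))
}

# meter offsets -> degrees around a reference latitude
offset_latlon <- function(lat0, lon0, dx_m, dy_m) {
  list(lat = lat0 + dy_m / M_PER_DEG,
       lon = lon0 + dx_m / (M_PER_DEG * cos(lat0 * pi / 180)))
}

#' Simulate one local day of GPS fixes
#'
#' Anchor-based trajectory: the participant starts at home and makes a
#' Poisson number of round trips to personal anchor locations during the day,
#' with the trip rate multiplied by `exp(mobility_anxiety * anxiety +
#' mobility_depression * depression)`. The total time away from home follows
#' a per-participant budget independent of the trip count, so location
#' entropy stays uncoupled from the planted mobility effects while distance
#' traveled and moving hours scale with the trip count. The raw trace (trip
#' waypoints plus jittered dwell fixes) is passed through the 20 m
#' displacement filter to emulate on-device sampling.
#'
#' @param profile One row of `simulate_cohort()$profiles`.
#' @param config A [sim_config()].
#' @param day Day index within the study window (1-based).
#' @return Tibble `sec` (local seconds since midnight), `lat`, `lon`,
#'   displacement-filtered; the substream seed is set internally from
#'   `(seed, pid, day)`.
#' @export
simulate_gps_day <- function(profile, config, day) {
  tibble::as_tibble(sim_gps_day_raw(as_prof(profile), config, day))
}

# plain-list profile for the per-day workhorses (tibble row access is slow
# inside the cohort loops)
as_prof <- function(profile) {
  if (is.list(profile) && !is.data.frame(profile)) return(profile)
  list(pid = profile$pid, latent_anxiety = profile$latent_anxiety,
       latent_depression = profile$latent_depression,
       latent_adhd = profile$latent_adhd,
       home_lat = profile$home_lat, home_lon = profile$home_lon,
       anchor_dlat = profile$anchor_dlat[[1]],
       anchor_dlon = profile$anchor_dlon[[1]],
       away_budget_s = profile$away_budget_s,
       baseline_lux = profile$baseline_lux,
       call_dur_mult = profile$call_dur_mult)
}

sim_gps_day_raw <- function(prof, config, day) {
  set.seed(mix_seed(config$seed, prof$pid, day * 10L + 1L))
  rt <- config$rates
  eff <- config$effects
  mob <- eff$mobility_anxiety * prof$latent_anxiety +
    eff$mobility_depression * prof$latent_depression
  n_trips <- rpois(1, rt$trips_per_day * exp(mob))
  hlat <- prof$home_lat; hlon <- prof$home_lon
  # the first fix of the day arrives at a variable overnight/morning time, so
  # hours before it are no-data and daily coverage varies as in real streams
  first_fix <- runif(1, 0, 2.5 * 3600)
  sec <- list(c(first_fix, sort(runif(3, first_fix, 7 * 3600))))
  lat <- list(rep(hlat, 4)); lon <- list(rep(hlon, 4))
  if (n_trips > 0) {
    away_day <- prof$away_budget_s * rlnorm(1, 0, 0.25)
    dwell_each <- min(away_day / n_trips, 3 * 3600)
    starts <- sort(runif(n_trips, 8 * 3600, 21 * 3600))
    cur <- 7.5 * 3600
    # one primary anchor (school/work) dominates, so the visited-place set --
    # and with it location entropy -- varies little with the trip count
    anchor_w <- c(rt$primary_anchor_weight,
                  rep((1 - rt$primary_anchor_weight) / (rt$n_anchors - 1),
                      rt$n_anchors - 1))
    for (k in seq_len(n_trips)) {
      s <- max(starts[k], cur + 600)
      j <- sample.int(rt$n_anchors, 1, prob = anchor_w)
      alat <- hlat + prof$anchor_dlat[j]; alon <- hlon + prof$anchor_dlon[j]
      d <- cpp_haversine(hlat, hlon, alat, alon)
      travel <- d / rt$trip_speed_ms
      if (s + 2 * travel + 300 > SECS_DAY - 600) break
      out_t <- seq(0, travel, by = 90)
      frac <- out_t / travel
      arrive <- s + travel
      dwell <- max(min(dwell_each * rlnorm(1, 0, 0.2),
                       SECS_DAY - 900 - arrive - travel), 0)
      dt <- if (dwell > 0) seq(0, dwell, by = 600) else numeric(0)
      back0 <- arrive + dwell
      # outbound leg, anchor dwell fixes, inbound leg, arrival back home
      sec <- c(sec, list(s + out_t, arrive + dt, back0 + out_t, back0 + travel + 60))
      lat <- c(lat, list(hlat + frac * (alat - hlat), rep(alat, length(dt)),
                         alat + frac * (hlat - alat), hlat))
      lon <- c(lon, list(hlon + frac * (alon - hlon), rep(alon, length(dt)),
                         alon + frac * (hlon - alon), hlon))
      cur <- back0 + travel + 60
    }
  }
  sec <- unlist(sec); lat <- unlist(lat); lon <- unlist(lon)
  ord <- order(sec)
  sec <- sec[ord]; lat <- lat[ord]; lon <- lon[ord]
  n <- length(sec)
  lat <- lat + rnorm(n, 0, 3) / M_PER_DEG
  lon <- lon + rnorm(n, 0, 3) / (M_PER_DEG * cos(lat * pi / 180))
  keep <- cpp_displacement_keep(lat, lon, 20)
  sec <- round(sec[keep]); lat <- lat[keep]; lon <- lon[keep]
  uniq <- c(TRUE, diff(sec) > 0)  # whole-second log resolution
  # 6-decimal coordinates (~0.1 m), the resolution real GPS logs carry
  list(sec = sec[uniq], lat = round(lat[uniq], 6), lon = round(lon[uniq], 6))
}

#' Simulate one local day of call events
#'
#' Incoming, outgoing and missed call counts are Poisson; the outgoing
#' log-rate decreases with latent depression
#' (`outgoing_depression` coupling). Connected-call durations are log-normal;
#' missed calls have duration 0.
#'
#' @inheritParams simulate_gps_day
#' @return Tibble `sec`, `direction`, `duration_s`, `contact_id`.
#' @export
simulate_calls_day <- function(profile, config, day) {
  tibble::as_tibble(sim_calls_day_raw(as_prof(profile), config, day))
}

sim_calls_day_raw <- function(prof, config, day) {
  set.seed(mix_seed(config$seed, prof$pid, day * 10L + 2L))
  rt <- config$rates
  lam_out <- rt$outgoing_per_day *
    exp(config$effects$outgoing_depression * prof$latent_depression)
  n_in <- rpois(1, rt$incoming_per_day)
  n_out <- rpois(1, lam_out)
  n_miss <- rpois(1, rt$missed_per_day)
  n <- n_in + n_out + n_miss
  if (n == 0) {
    return(list(sec = double(0), direction = character(0),
                duration_s = double(0), contact_id = character(0)))
  }
  direction <- sample(c(rep("incoming", n_in), rep("outgoing", n_out),
                        rep("missed", n_miss)))
  meanlog <- ifelse(direction == "incoming", rt$call_duration_meanlog_in,
                    rt$call_duration_meanlog_out)
  dur <- round(prof$call_dur_mult *
                 rlnorm(n, meanlog, rt$call_duration_sdlog)) + 1
  dur[direction == "missed"] <- 0
  list(sec = round(sort(runif(n, 8 * 3600, 22 * 3600))),
       direction = direction,
       duration_s = dur,
       contact_id = paste0("c", sample.int(25, n, replace = TRUE)))
}

#' Simulate one local day of screen on/off events
#'
#' A Poisson number of use sessions with log-normal durations scaled by
#' `exp(screen_anxiety * anxiety)`, placed over the waking day without
#' overlap; emitted as alternating on/off events. The session *count* carries
#' no planted coupling (only total screen time does), so unlock counts act as
#' a null feature.
#'
#' @inheritParams simulate_gps_day
#' @return Tibble `sec`, `state`.
#' @export
simulate_screen_day <- function(profile, config, day) {
  tibble::as_tibble(sim_screen_day_raw(as_prof(profile), config, day))
}

sim_screen_day_raw <- function(prof, config, day) {
  set.seed(mix_seed(config$seed, prof$pid, day * 10L + 3L))
  rt <- config$rates
  n <- rpois(1, rt$screen_sessions_per_day)
  if (n == 0) return(list(sec = double(0), state = character(0)))
  start <- sort(runif(n, 6 * 3600, SECS_DAY - 120))
  dur <- rlnorm(n, rt$screen_session_meanlog, rt$screen_session_sdlog) *
    exp(config$effects$screen_anxiety * prof$latent_anxiety)
  limit <- c(start[-1] - 1, SECS_DAY - 1)
  end <- pmin(start + dur, limit)
  ok <- end > start
  start <- floor(start[ok]); end <- ceiling(end[ok])
  list(sec = as.vector(rbind(start, end)),
       state = rep(c("on", "off"), length(start)))
}

#' Simulate one night of ambient-light samples
#'
#' A step process over the 11 PM-7 AM window attributed to this day: a dark
#' baseline sample at the window start, plus a Poisson number of light
#' episodes (lamps, phone use in bed) whose rate grows with latent depression
#' (`night_light_depression` coupling). Episode intensities are log-normal;
#' each episode emits a change sample at its start and a return-to-baseline
#' sample at its end.
#'
#' @inheritParams simulate_gps_day
#' @return Tibble `sec` (local seconds since this day's midnight; values past
#'   86400 fall after the following midnight), `lux`.
#' @export
simulate_light_day <- function(profile, config, day) {
  tibble::as_tibble(sim_light_day_raw(as_prof(profile), config, day))
}

sim_light_day_raw <- function(prof, config, day) {
  set.seed(mix_seed(config$seed, prof$pid, day * 10L + 4L))
  rt <- config$rates
  lam <- rt$light_episodes_per_night *
    exp(config$effects$night_light_depression * prof$latent_depression)
  n_ep <- rpois(1, lam)
  base <- prof$baseline_lux
  w0 <- 23 * 3600
  w1 <- w0 + 8 * 3600
  sec <- w0; lux <- base
  if (n_ep > 0) {
    ep_start <- sort(runif(n_ep, w0 + 60, w1 - 300))
    ep_dur <- runif(n_ep, rt$episode_dur_min[1], rt$episode_dur_min[2]) * 60
    ep_end <- pmin(ep_start + ep_dur, w1 - 1)
    ep_lux <- rlnorm(n_ep, rt$episode_lux_meanlog, rt$episode_lux_sdlog)
    sec <- c(sec, as.vector(rbind(ep_start, ep_end)))
    lux <- c(lux, as.vector(rbind(ep_lux, rep(base, n_ep))))
  }
  ord <- order(sec)
  list(sec = round(sec[ord]), lux = round(lux[ord], 3))
}

#' Simulate item-level survey responses
#'
#' Graded item responses whose totals regress on the latent symptom scores
#' with loading `survey_loading`: SCARED items are Binomial(2, plogis(1.06 s)),
#' CES-DC severities Binomial(3, plogis(0.23 + 1.30 s)) (stored with the
#' standard reverse-keyed items 4/8/12/16 inverted so scoring restores them),
#' ASRS items Binomial(4, plogis(-0.4 + 1.0 s)), where `s` is the loaded
#' latent plus independent noise. The logistic constants calibrate the SCARED
#' and CES-DC total means and SDs to the emulated study's printed values
#' (33.0/14.8 and 32.6/15.2).
#'
#' @param profiles `simulate_cohort()$profiles`.
#' @param config A [sim_config()].
#' @return Long survey tibble: `participant_id`, `instrument`,
#'   `item_1..item_33` (shorter instruments padded with `NA`).
#' @export
simulate_surveys <- function(profiles, config) {
  lam <- config$survey_loading
  rows <- lapply(seq_len(nrow(profiles)), function(i) {
    p <- profiles[i, ]
    set.seed(mix_seed(config$seed, p$pid, 99991L))
    mix <- function(latent) lam * latent + sqrt(1 - lam^2) * rnorm(1)
    s_anx <- mix(p$latent_anxiety)
    s_dep <- mix(p$latent_depression)
    s_adhd <- mix(p$latent_adhd)
    scared <- rbinom(33, 2, plogis(1.06 * s_anx))
    sev <- rbinom(20, 3, plogis(0.23 + 1.30 * s_dep))
    cesdc <- sev
    cesdc[c(4, 8, 12, 16)] <- 3 - sev[c(4, 8, 12, 16)]
    asrs <- rbinom(18, 4, plogis(-0.4 + 1.0 * s_adhd))
    pad <- function(x) c(x, rep(NA_integer_, 33 - length(x)))
    m <- rbind(SCARED33 = pad(scared), CESDC = pad(cesdc), ASRS = pad(asrs))
    out <- tibble::as_tibble(m, .name_repair = ~ paste0("item_", seq_len(33)))
    dplyr::bind_cols(
      tibble::tibble(participant_id = p$participant_id,
                     instrument = rownames(m)), out)
  })
  dplyr::bind_rows(rows)
}

# inject stream malformations (duplicate events, unpaired screen-on,
# out-of-order rows) to exercise the repair/validation paths
malform_streams <- function(streams, pid, seed) {
  set.seed(mix_seed(seed, pid, 777001L))
  if (nrow(streams$screen) > 2) {
    i <- sample.int(nrow(streams$screen) - 1, 1)
    streams$screen <- dplyr::bind_rows(streams$screen[seq_len(i), ],
                                       streams$screen[i, ],
                                       streams$screen[-seq_len(i), ])
  }
  if (nrow(streams$calls) > 1) {
    streams$calls <- streams$calls[sample.int(nrow(streams$calls)), ]
  }
  streams
}

#' Simulate a full synthetic sensing study
#'
#' Generates the complete study: cohort metadata, latent profiles, retention
#' ledger, item-level surveys, and per-participant 14-day sensor bundles
#' (each participant contributes `days_provided` days; participants flagged
#' as missing required sensors contribute empty GPS and call streams). Fully
#' deterministic given the config seed.
#'
#' @param config A [sim_config()].
#' @return A `digiphen_study` list: `config`, `meta`, `profiles`, `ledger`,
#'   `surveys`, `truth` (the planted coupling table) and `bundles` (named
#'   list of `sensor_bundle`s).
#' @export
simulate_study <- function(config = sim_config()) {
  cohort <- simulate_cohort(config)
  surveys <- simulate_surveys(cohort$profiles, config)
  pr <- cohort$profiles
  bundles <- lapply(seq_len(nrow(pr)), function(i) {
    p <- list(pid = pr$pid[i], latent_anxiety = pr$latent_anxiety[i],
              latent_depression = pr$latent_depression[i],
              latent_adhd = pr$latent_adhd[i],
              home_lat = pr$home_lat[i], home_lon = pr$home_lon[i],
              anchor_dlat = pr$anchor_dlat[[i]],
              anchor_dlon = pr$anchor_dlon[[i]],
              away_budget_s = pr$away_budget_s[i],
              baseline_lux = pr$baseline_lux[i],
              call_dur_mult = pr$call_dur_mult[i])
    meta <- cohort$meta[i, ]
    led_days <- cohort$ledger$days_provided[i]
    led_sensors <- cohort$ledger$has_required_sensors[i]
    nd <- led_days
    day0 <- as.numeric(meta$study_start) * SECS_DAY - meta$tz_offset_min * 60
    days <- seq_len(nd)
    shift <- function(d, s) day0 + (d - 1) * SECS_DAY + s
    raw <- lapply(days, function(d) list(
      gps = sim_gps_day_raw(p, config, d),
      calls = sim_calls_day_raw(p, config, d),
      screen = sim_screen_day_raw(p, config, d),
      light = sim_light_day_raw(p, config, d)))
    pull <- function(stream, field, proto = numeric(0)) {
      unlist(lapply(seq_along(raw), function(d) raw[[d]][[stream]][[field]]),
             use.names = FALSE) %||% proto
    }
    pull_t <- function(stream) {
      s <- unlist(lapply(seq_along(raw), function(d)
        shift(d, raw[[d]][[stream]]$sec)), use.names = FALSE) %||% numeric(0)
      as_utc_posix(s)
    }
    gps <- fast_tibble(timestamp = pull_t("gps"), lat = pull("gps", "lat"),
                          lon = pull("gps", "lon"))
    calls <- fast_tibble(timestamp = pull_t("calls"),
                            direction = pull("calls", "direction", character(0)),
                            duration_s = pull("calls", "duration_s"),
                            contact_id = pull("calls", "contact_id", character(0)))
    screen <- fast_tibble(timestamp = pull_t("screen"),
                             state = pull("screen", "state", character(0)))
    light <- fast_tibble(timestamp = pull_t("light"),
                            lux = pull("light", "lux"))
    if (!led_sensors) {
      gps <- gps[0, ]
      calls <- calls[0, ]
    }
    streams <- list(gps = gps, calls = calls, screen = screen, light = light)
    if (config$malformed) {
      # leave malformed streams raw (a plain list, not a validated bundle)
      # so the IO repair and validation paths can be exercised by the caller
      streams <- malform_streams(streams, p$pid, config$seed)
      return(c(list(meta = meta), streams))
    }
    new_sensor_bundle(meta, streams$gps, streams$calls, streams$screen,
                      streams$light, study_days = config$days)
  })
  names(bundles) <- cohort$profiles$participant_id
  truth <- tibble::tibble(
    feature = c("time_sedentary_h", "time_moving_h", "distance_km",
                "n_outgoing", "mean_night_lux", "screen_time_min",
                "time_sedentary_h", "time_moving_h", "distance_km",
                "entropy_norm", "entropy_norm", "call_duration_min",
                "n_incoming", "n_unlocks"),
    outcome = c(rep("cesdc_total", 6),
                rep("scared_total", 3),
                "cesdc_total", "scared_total", "cesdc_total",
                "cesdc_total", "cesdc_total"),
    direction = c(+1, -1, -1, -1, +1, 0, -1, +1, +1, 0, 0, 0, 0, 0),
    magnitude = c(abs(config$effects$mobility_depression),
                  abs(config$effects$mobility_depression),
                  abs(config$effects$mobility_depression),
                  abs(config$effects$outgoing_depression),
                  abs(config$effects$night_light_depression), 0,
                  abs(config$effects$mobility_anxiety),
                  abs(config$effects$mobility_anxiety),
                  abs(config$effects$mobility_anxiety), 0, 0, 0, 0, 0))
  truth$direction[truth$feature == "screen_time_min" &
                    truth$outcome == "cesdc_total"] <- 0
  truth <- dplyr::bind_rows(
    truth,
    tibble::tibble(feature = "screen_time_min", outcome = "scared_total",
                   direction = +1,
                   magnitude = abs(config$effects$screen_anxiety)))
  structure(list(config = config, meta = cohort$meta,
                 profiles = cohort$profiles, ledger = cohort$ledger,
                 surveys = surveys, truth = truth, bundles = bundles),
            class = "digiphen_study")
}

#' @export
print.digiphen_study <- function(x, ...) {
  cat(sprintf("<digiphen_study> %d participants, %d-day window, seed %s\n",
              x$config$n_participants, x$config$days,
              format(x$config$seed)))
  ret <- apply_retention_filters(x$ledger, x$config$days)
  cat(sprintf("  retained: %d (%s)\n", sum(ret$retained),
              paste(names(attr(ret, "exclusions")), attr(ret, "exclusions"),
                    sep = "=", collapse = " ")))
  invisible(x)
}

#' Write a simulated study to disk in the study's CSV schemas
#'
#' Emits `meta.csv`, `ledger.csv`, `surveys.csv`, `truth.csv` and one
#' directory per participant holding `gps.csv`, `calls.csv`, `screen.csv`,
#' `light.csv`, so the disk layout round-trips through
#' [read_sensor_bundle()].
#'
#' @param study A `digiphen_study`.
#' @param dir Output directory.
#' @return Invisibly, `dir`.
#' @export
write_simulated_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(study$meta, file.path(dir, "meta.csv"), progress = FALSE)
  readr::write_csv(study$ledger, file.path(dir, "ledger.csv"), progress = FALSE)
  readr::write_csv(study$surveys, file.path(dir, "surveys.csv"), progress = FALSE)
  readr::write_csv(study$truth, file.path(dir, "truth.csv"), progress = FALSE)
  for (id in names(study$bundles)) {
    write_sensor_bundle(study$bundles[[id]], file.path(dir, id))
  }
  invisible(dir)
}
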