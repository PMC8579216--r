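test_that("the generator is deterministic and stable under cohort growth", {
  cfg <- small_config(n = 8)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(small_config(n = 8))
  expect_equal(s1$meta, s2$meta)
  expect_equal(s1$surveys, s2$surveys)
  for (id in names(s1$bundles)) {
    expect_equal(s1$bundles[[id]]$gps, s2$bundles[[id]]$gps, info = id)
  }
  # per participant-day substreams: enlarging the cohort leaves the first
  # participants' data untouched
  s3 <- simulate_study(small_config(n = 12))
  expect_equal(s3$bundles[["P0003"]]$gps, s1$bundles[["P0003"]]$gps)
  expect_equal(s3$bundles[["P0003"]]$light, s1$bundles[["P0003"]]$light)
})

test_that("generated streams satisfy the schema invariants", {
  cfg <- small_config(n = 10)
  study <- simulate_study(cfg)
  for (b in study$bundles) {
    expect_s3_class(b, "sensor_bundle") # construction implies validation
    # consecutive retained fixes exceed the 20 m displacement threshold
    g <- b$gps
    if (nrow(g) > 1) {
      # displacement sampling applies within a local day's stream
      day <- floor(as.numeric(g$timestamp) / 86400)
      same_day <- day[-1] == day[-length(day)]
      d <- haversine_m(g$lat[-nrow(g)], g$lon[-nrow(g)],
                       g$lat[-1], g$lon[-1])
      expect_true(all(d[same_day] > 20 - 1)) # 1 m slack for coordinate rounding
    }
    # screen events alternate and pair without repair warnings
    scr <- extract_screen(b$screen)
    expect_equal(sum(attr(scr, "repairs")), 0)
    # missed calls carry zero duration
    expect_true(all(b$calls$duration_s[b$calls$direction == "missed"] == 0))
  }
  # n_connected = n_incoming + n_outgoing under the adopted definition
  daily <- purrr::map_dfr(study$bundles, extract_features)
  expect_true(all(daily$n_connected == daily$n_incoming + daily$n_outgoing,
                  na.rm = TRUE))
})

test_that("cohort demographics and retention match their targets", {
  cfg <- sim_config(n_participants = 4000, seed = 5)
  cohort <- simulate_cohort(cfg)
  expect_equal(mean(cohort$meta$age), 18, tolerance = 0.15 / 18)
  expect_equal(mean(cohort$meta$sex == "female"), 96 / 122, tolerance = 0.03)
  expect_equal(mean(cohort$meta$os == "ios"), 96 / 122, tolerance = 0.03)
  expect_true(all(cohort$meta$age >= 10 & cohort$meta$age <= 21))
  ret <- apply_retention_filters(cohort$ledger)
  expect_equal(mean(ret$retained), 122 / 161, tolerance = 0.03 / (122 / 161))
  # latent anxiety-depression correlation near its configured 0.5
  expect_equal(cor(cohort$profiles$latent_anxiety,
                   cohort$profiles$latent_depression), 0.5, tolerance = 0.12)
})

test_that("survey totals are calibrated to the instrument distributions", {
  cfg <- sim_config(n_participants = 5000, seed = 6)
  cohort <- simulate_cohort(cfg)
  sc <- score_surveys(simulate_surveys(cohort$profiles, cfg))
  expect_equal(mean(sc$scared_total), 33, tolerance = 1 / 33)
  expect_equal(sd(sc$scared_total), 14.79, tolerance = 0.08)
  expect_equal(mean(sc$cesdc_total), 32.6, tolerance = 1 / 32.6)
  expect_true(all(sc$scared_total >= 0 & sc$scared_total <= 66))
  expect_true(all(sc$cesdc_total >= 0 & sc$cesdc_total <= 60))
  expect_true(all(sc$asrs_total >= 0 & sc$asrs_total <= 72))
  # zero loading decouples totals from the latents
  cfg0 <- sim_config(n_participants = 1500, seed = 6, survey_loading = 0)
  cohort0 <- simulate_cohort(cfg0)
  sc0 <- score_surveys(simulate_surveys(cohort0$profiles, cfg0))
  r0 <- cor(sc0$scared_total, cohort0$profiles$latent_anxiety)
  expect_lt(abs(r0), 0.06)
})

test_that("planted couplings steer the day generators as configured", {
  cfg <- small_config(n = 2, effects = list(mobility_depression = -1))
  prof_hi <- tibble::tibble(participant_id = "hi", pid = 1L,
                            latent_anxiety = 0, latent_depression = 6,
                            latent_adhd = 0, home_lat = 44.65,
                            home_lon = -63.57,
                            anchor_dlat = list(rep(0.01, 5)),
                            anchor_dlon = list(rep(0.01, 5)),
                            away_budget_s = 3 * 3600, baseline_lux = 2,
                            call_dur_mult = 1)
  prof_lo <- dplyr::mutate(prof_hi, latent_depression = -4)
  # extreme depression suppresses trips: a near-full-day single cluster
  g_hi <- simulate_gps_day(prof_hi, cfg, 1)
  cl <- cluster_locations(gps_from_offsets(g_hi$sec, 0, 0) |>
                            dplyr::mutate(lat = g_hi$lat, lon = g_hi$lon))
  expect_lte(max(cl$cluster), 2L)
  # and the same participant with low depression travels more
  dist_of <- function(g) {
    if (nrow(g) < 2) return(0)
    sum(haversine_m(g$lat[-nrow(g)], g$lon[-nrow(g)], g$lat[-1], g$lon[-1]))
  }
  d_hi <- mean(vapply(1:6, function(d) dist_of(simulate_gps_day(prof_hi, cfg, d)), 0))
  d_lo <- mean(vapply(1:6, function(d) dist_of(simulate_gps_day(prof_lo, cfg, d)), 0))
  expect_gt(d_lo, d_hi)
  # outgoing-call rate falls with depression; at zero coupling the Poisson
  # mean matches the base rate within Monte Carlo error
  cfg0 <- small_config(n = 2, effects = list(outgoing_depression = 0))
  outs <- vapply(1:600, function(d) {
    x <- simulate_calls_day(prof_hi, cfg0, d)
    sum(x$direction == "outgoing")
  }, 0)
  base <- cfg0$rates$outgoing_per_day
  expect_equal(mean(outs), base, tolerance = 2.5 * sqrt(base / 600) / base)
})

test_that("malformation injection produces repairable streams", {
  cfg <- small_config(n = 4, malformed = TRUE)
  study <- simulate_study(cfg)
  raw <- study$bundles[[1]]
  expect_false(inherits(raw, "sensor_bundle"))
  # out-of-order call rows fail validation until sorted
  expect_error(new_sensor_bundle(raw$meta, raw$gps, raw$calls, raw$screen,
                                 raw$light),
               NA) # calls have no ordering invariant; screen does
  scr_dup <- raw$screen
  s <- pair_screen_sessions(scr_dup)
  expect_gte(sum(attr(s, "repairs")), 1)
})
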