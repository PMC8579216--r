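test_that("screen sessions pair on/off events and split at midnight", {
  ev <- screen_events(c(10 * 3600, 10 * 3600 + 300, 22 * 3600, 22.5 * 3600),
                      c("on", "off", "on", "off"))
  s <- pair_screen_sessions(ev)
  expect_equal(nrow(s), 2L)
  d <- extract_screen(ev)
  expect_equal(d$n_unlocks, 2L)
  expect_equal(d$screen_time_min, 35, tolerance = 1e-9)
  # midnight straddle: 23:50 on, 00:10 off next day -> 10 min on each date
  ev2 <- screen_events(c(23 * 3600 + 50 * 60, 24 * 3600 + 10 * 60),
                       c("on", "off"))
  d2 <- extract_screen(ev2)
  expect_equal(nrow(d2), 2L)
  expect_equal(d2$screen_time_min, c(10, 10))
  expect_equal(d2$n_unlocks, c(1L, 0L)) # one physical unlock, on day one
  # a trailing unmatched "on" closes at the next local midnight
  ev3 <- screen_events(23 * 3600, "on")
  d3 <- extract_screen(ev3)
  expect_equal(d3$screen_time_min, 60)
  expect_equal(attr(d3, "repairs")[["unmatched_on"]], 1L)
})

test_that("same-state runs deduplicate to the first event", {
  # enumerate every on/off pattern of length three
  states <- expand.grid(a = c("on", "off"), b = c("on", "off"),
                        c = c("on", "off"), stringsAsFactors = FALSE)
  oracle <- function(st) {
    # manual pairing after keeping the first of each run and dropping a
    # leading off; returns total on-minutes given events at 10:00/10:10/10:20
    t <- c(600, 610, 620)
    keep <- c(TRUE, st[-1] != st[-3])
    t <- t[keep]; st <- st[keep]
    if (length(st) && st[1] == "off") { t <- t[-1]; st <- st[-1] }
    if (!length(st)) return(0)
    if (st[length(st)] == "on") { t <- c(t, 1440); st <- c(st, "off") }
    sum(t[st == "off"] - t[st == "on"])
  }
  for (i in seq_len(nrow(states))) {
    st <- unlist(states[i, ], use.names = FALSE)
    ev <- screen_events(c(600, 610, 620) * 60, st)
    d <- extract_screen(ev)
    got <- if (nrow(d)) sum(d$screen_time_min) else 0
    expect_equal(got, oracle(st), info = paste(st, collapse = ","))
  }
  # explicit spec case: on, on, off is one session from the first on
  s <- pair_screen_sessions(screen_events(c(600, 605, 610) * 60,
                                          c("on", "on", "off")))
  expect_equal(nrow(s), 1L)
  expect_equal(s$duration_s, 600)
})

test_that("screen features are invariant to redundant same-state events", {
  set.seed(6)
  on <- sort(runif(10, 6 * 3600, 20 * 3600))
  off <- on + runif(10, 60, 500)
  ev <- screen_events(as.vector(rbind(on, off)),
                      rep(c("on", "off"), 10))
  base <- extract_screen(ev)
  # duplicate every third event (same state, same or later time)
  dup <- dplyr::arrange(dplyr::bind_rows(ev, ev[seq(1, 20, by = 3), ]),
                        timestamp, dplyr::desc(state))
  with_dup <- extract_screen(dup)
  expect_equal(with_dup$n_unlocks, base$n_unlocks)
  expect_equal(with_dup$screen_time_min, base$screen_time_min)
})

test_that("daily call features follow the connected-call definition", {
  cl <- call_events(c(10, 11, 12) * 3600,
                    c("outgoing", "outgoing", "missed"), c(60, 120, 0))
  d <- extract_calls(cl)
  expect_equal(d$n_outgoing, 2L)
  expect_equal(d$n_connected, 2L)
  expect_equal(d$n_missed, 1L)
  expect_equal(d$call_duration_min, 3.0)
  expect_equal(nrow(extract_calls(cl[0, ])), 0L)
  # a zero-duration incoming call is logged but not connected
  cl2 <- call_events(c(9, 10) * 3600, c("incoming", "incoming"), c(0, 30))
  d2 <- extract_calls(cl2)
  expect_equal(d2$n_incoming, 1L)
  expect_equal(d2$n_connected, 1L)
  expect_error(extract_calls(call_events(9 * 3600, "missed", 5)),
               "duration 0")
})

test_that("night light features integrate the held step function", {
  # constant 100 lux all night
  l <- light_samples(23 * 3600, 100)
  d <- extract_light(l)
  expect_equal(d$mean_night_lux, 100)
  expect_equal(d$time_low_lux_min, 0)
  expect_equal(d$time_high_lux_min, 0)
  # 0 lux for 4 h then 2000 lux for 4 h: mean 1000, 240 min in each range
  l2 <- light_samples(c(23, 27) * 3600, c(0, 2000))
  d2 <- extract_light(l2)
  expect_equal(d2$mean_night_lux, 1000)
  expect_equal(d2$time_low_lux_min, 240)
  expect_equal(d2$time_high_lux_min, 240)
  expect_equal(d2$time_low_lux_min + d2$time_high_lux_min, 480)
  # carry-in: a pre-window sample holds into the window head
  l3 <- light_samples(c(22, 25) * 3600, c(5, 500))
  d3 <- extract_light(l3)
  expect_equal(d3$night_coverage_min, 480)
  expect_equal(d3$mean_night_lux, (5 * 2 + 500 * 6) * 60 / 480)
  # the night belongs to the date containing 11 PM
  expect_equal(d3$date, as.Date("2020-03-02"))
  # a night with no in-window samples is missing entirely
  expect_equal(nrow(extract_light(light_samples(12 * 3600, 50))), 0L)
})

test_that("time-weighted night mean lies within the observed sample range", {
  set.seed(7)
  for (rep in 1:10) {
    k <- sample(2:8, 1)
    sec <- sort(runif(k, 23 * 3600, 31 * 3600 - 60))
    lux <- rlnorm(k, 3, 1)
    d <- extract_light(light_samples(sec, lux))
    expect_gte(d$mean_night_lux, min(lux))
    expect_lte(d$mean_night_lux, max(lux))
    expect_lte(d$time_low_lux_min + d$time_high_lux_min, 480)
  }
})
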