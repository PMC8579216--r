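test_that("haversine matches the closed-form meridian arc and is symmetric", {
  arc <- pi / 180 * 6371000 # one degree of great circle on the 6371 km sphere
  expect_equal(haversine_m(0, 0, 0, 1), arc, tolerance = 0.1 / arc)
  expect_equal(haversine_m(0, 0, 1, 0), arc, tolerance = 0.1 / arc)
  expect_identical(haversine_m(10.2, -5, 10.2, -5), 0)
  set.seed(1)
  a <- cbind(runif(100, -90, 90), runif(100, -180, 180))
  b <- cbind(runif(100, -90, 90), runif(100, -180, 180))
  expect_equal(haversine_m(a[, 1], a[, 2], b[, 1], b[, 2]),
               haversine_m(b[, 1], b[, 2], a[, 1], a[, 2]))
  expect_error(haversine_m(95, 0, 0, 0), "out of bounds")
})

test_that("haversine agrees with an independent geodesic implementation", {
  skip_if_not_installed("geosphere")
  set.seed(2)
  a <- cbind(runif(50, -180, 180), runif(50, -89, 89)) # lon, lat for geosphere
  b <- cbind(runif(50, -180, 180), runif(50, -89, 89))
  ref <- geosphere::distHaversine(a, b, r = 6371000)
  expect_equal(haversine_m(a[, 2], a[, 1], b[, 2], b[, 1]), ref,
               tolerance = 1e-9)
})

test_that("displacement filter keeps only fixes > threshold from last kept", {
  # brute-force sequential oracle
  oracle <- function(lat, lon, th) {
    keep <- 1L
    last <- 1L
    for (i in seq_along(lat)[-1]) {
      if (haversine_m(lat[last], lon[last], lat[i], lon[i]) > th) {
        keep <- c(keep, i); last <- i
      }
    }
    keep
  }
  # stationary trace: everything within 5 m
  g <- gps_from_offsets(sec = 0:19 * 60, dx_m = runif(20, 0, 5), dy_m = 0)
  expect_equal(nrow(filter_displacement(g, 20)), 1L)
  # points spaced exactly at the threshold: the strictly-greater rule keeps
  # only the first (threshold set to the exact pairwise distance)
  g20 <- gps_from_offsets(sec = c(0, 60), dx_m = c(0, 20), dy_m = 0)
  d20 <- haversine_m(g20$lat[1], g20$lon[1], g20$lat[2], g20$lon[2])
  expect_equal(nrow(filter_displacement(g20, d20)), 1L)
  # oscillating just under the threshold: nothing ever leaves the first fix's
  # 20 m circle, so only the first is retained
  g19 <- gps_from_offsets(sec = 0:9 * 60, dx_m = rep(c(0, 19.9), 5), dy_m = 0)
  expect_equal(nrow(filter_displacement(g19, 20)), 1L)
  # 25 m spacing keeps everything
  g25 <- gps_from_offsets(sec = 0:9 * 60, dx_m = 0:9 * 25, dy_m = 0)
  expect_equal(nrow(filter_displacement(g25, 20)), 10L)
  # random walks match the brute-force scan
  set.seed(3)
  for (rep in 1:5) {
    g <- gps_from_offsets(sec = 1:60, dx_m = cumsum(rnorm(60, 0, 15)),
                          dy_m = cumsum(rnorm(60, 0, 15)))
    got <- filter_displacement(g, 20)
    expect_equal(got$lat, g$lat[oracle(g$lat, g$lon, 20)])
  }
  expect_equal(nrow(filter_displacement(g[0, ], 20)), 0L)
})

test_that("greedy clustering groups nearby fixes and splits distant ones", {
  g1 <- gps_from_offsets(sec = 0:9, dx_m = runif(10, 0, 10), dy_m = 0)
  c1 <- cluster_locations(g1, 150)
  expect_true(all(c1$cluster == 1L))
  # two groups 1 km apart
  g2 <- gps_from_offsets(sec = 0:9, dx_m = c(rep(0, 5), rep(1000, 5)),
                         dy_m = 0)
  c2 <- cluster_locations(g2, 150)
  expect_equal(unique(c2$cluster), c(1L, 2L))
  # appending duplicates at an existing centroid leaves the count unchanged
  g3 <- dplyr::bind_rows(g2, g2[1, ])
  expect_equal(max(cluster_locations(g3, 150)$cluster), 2L)
  # members stay within 2x radius of the final (drifted running-mean) centroid
  set.seed(4)
  g4 <- gps_from_offsets(sec = 1:200, dx_m = cumsum(rnorm(200, 3, 40)),
                         dy_m = cumsum(rnorm(200, 0, 40)))
  c4 <- cluster_locations(g4, 150)
  cent <- attr(c4, "centroids")
  d <- haversine_m(c4$lat, c4$lon, cent$centroid_lat[c4$cluster],
                   cent$centroid_lon[c4$cluster])
  expect_true(all(d <= 2 * 150))
})

test_that("normalized entropy has the analytic endpoints and is base-free", {
  expect_identical(normalized_entropy(1), 0)
  for (n in c(2, 3, 5, 10, 50)) {
    expect_equal(normalized_entropy(rep(1 / n, n)), 1)
  }
  expect_equal(normalized_entropy(c(0.75, 0.25)), 0.8113, tolerance = 1e-4)
  # base invariance: the log base cancels in the normalized ratio
  base2 <- function(p) {
    p <- p[p > 0]
    -sum(p * log2(p)) / log2(length(p))
  }
  expect_equal(normalized_entropy(c(0.75, 0.25)), base2(c(0.75, 0.25)))
  # permutation invariance and [0, 1] bounds on random distributions
  set.seed(5)
  for (rep in 1:20) {
    p <- runif(sample(2:8, 1))
    p <- p / sum(p)
    h <- normalized_entropy(p)
    expect_true(h >= 0 && h <= 1)
    expect_equal(normalized_entropy(sample(p)), h)
  }
  # adding a far cluster with positive dwell to a uniform spread cannot
  # decrease raw entropy; uniform stays exactly 1
  raw <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  p0 <- rep(0.25, 4)
  p1 <- c(p0 * 0.9, 0.1)
  expect_gte(raw(p1), raw(p0))
  expect_error(normalized_entropy(c(0.5, 0.4)), "sum to 1")
  expect_error(normalized_entropy(c(1.2, -0.2)), "nonnegative")
})

test_that("locations per hour counts clusters by clipped within-hour dwell", {
  # 30 min at A, 25 min at B, 5 min at C within hour 10: all three qualify
  sec <- c(10 * 3600, 10 * 3600 + 1800, 10 * 3600 + 3300)
  cl <- c(1L, 2L, 3L) # C holds from 10:55 to 11:00 via carry-forward clipping
  expect_equal(locations_per_hour(sec, cl, hour = 10), 3)
  # a 90 s visit is excluded: only the home cluster qualifies
  sec2 <- c(10 * 3600, 10 * 3600 + 1800, 10 * 3600 + 1890)
  expect_equal(locations_per_hour(sec2, c(1L, 2L, 1L), hour = 10), 1)
  # visit straddling an hour boundary with one minute each side is excluded
  # from both hours (clipping), while its neighbours still count
  sec3 <- c(10 * 3600, 11 * 3600 - 60, 11 * 3600 + 60)
  cl3 <- c(1L, 2L, 3L)
  expect_equal(locations_per_hour(sec3, cl3, hour = 10, min_dwell_s = 120), 1)
  dw <- digiphen:::hour_dwell_matrix(sec3, cl3)
  expect_equal(dw[2, 11], 60) # cluster 2, hour 10: one clipped minute
  expect_equal(dw[2, 12], 60) # cluster 2, hour 11: the other minute
  # a whole hour at one cluster
  expect_equal(locations_per_hour(9 * 3600, 1L, hour = 9), 1)
  expect_equal(locations_per_hour(numeric(0), integer(0), hour = 9), 0L)
})

test_that("hour classification partitions counts contiguously", {
  expect_equal(classify_hour(c(0, 1, 5, 9, 10, 12)),
               c("no_data", "stationary", "moving", "moving",
                 "transportation", "transportation"))
})

test_that("daily mobility summarizes distance, entropy and hour classes", {
  # a participant who never moves: one fix carried forward all day
  g <- gps_from_offsets(sec = 0, dx_m = 0, dy_m = 0)
  m <- extract_mobility(g)
  expect_equal(m$distance_km, 0)
  expect_equal(m$entropy_norm, 0)
  expect_equal(m$time_sedentary_h, m$hours_observed)
  expect_equal(m$hours_observed, 24L)
  # two fixes 3 km apart, else stationary: distance 3 km
  g2 <- gps_from_offsets(sec = c(0, 12 * 3600), dx_m = c(0, 3000), dy_m = 0)
  m2 <- extract_mobility(g2)
  expect_equal(m2$distance_km, 3.0, tolerance = 1e-6)
  # empty stream: zero rows
  expect_equal(nrow(extract_mobility(g[0, ])), 0L)
  # the day is split at local midnight in the participant's timezone
  g3 <- dplyr::bind_rows(
    gps_from_offsets(sec = 23.5 * 3600, dx_m = 0, dy_m = 0),
    gps_from_offsets(sec = 0.5 * 3600, dx_m = 5000, dy_m = 0,
                     day0 = as.Date("2020-03-03")))
  m3 <- extract_mobility(g3)
  expect_equal(nrow(m3), 2L)
  expect_equal(as.integer(diff(m3$date)), 1L)
})
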