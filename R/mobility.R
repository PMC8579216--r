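#' Great-circle (Haversine) distance in meters
#'
#' Distance between pairs of latitude/longitude coordinates on a spherical
#' Earth of radius 6,371,000 m, the standard metric for displacement-triggered
#' GPS streams. All arguments are recycled to a common length.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees; latitudes in
#'   \[-90, 90\], longitudes in \[-180, 180\].
#' @return Numeric vector of distances in meters.
#' @examples
#' haversine_m(0, 0, 0, 1) # one degree of longitude at the equator
#' @export
haversine_m <- function(lat1, lon1, lat2, lon2) {
  n <- max(length(lat1), length(lon1), length(lat2), length(lon2))
  lat1 <- rep_len(lat1, n); lon1 <- rep_len(lon1, n)
  lat2 <- rep_len(lat2, n); lon2 <- rep_len(lon2, n)
  if (any(abs(c(lat1, lat2)) > 90, na.rm = TRUE) ||
      any(abs(c(lon1, lon2)) > 180, na.rm = TRUE)) {
    stop_bad_arg("coordinates out of bounds: |lat| <= 90 and |lon| <= 180 required")
  }
  cpp_haversine(lat1, lon1, lat2, lon2)
}

#' Emulate displacement-triggered GPS sampling
#'
#' Keeps the first fix and every subsequent fix whose Haversine distance from
#' the previously kept fix strictly exceeds `threshold_m`. This reproduces the
#' on-device sampling rule of apps that log a fix only after the phone moves
#' beyond a displacement radius (20 m here), and is applied both by the
#' synthetic generator (to emulate the app) and defensively at extraction time
#' (idempotent on already-filtered streams).
#'
#' @param gps Tibble with columns `timestamp`, `lat`, `lon`, time-ordered.
#' @param threshold_m Displacement threshold in meters (default 20).
#' @return The filtered tibble (same columns, subset of rows).
#' @export
filter_displacement <- function(gps, threshold_m = 20) {
  stopifnot(all(c("lat", "lon") %in% names(gps)))
  if (nrow(gps) == 0) return(gps)
  keep <- cpp_displacement_keep(gps$lat, gps$lon, threshold_m)
  gps[keep, , drop = FALSE]
}

#' Greedy sequential location clustering
#'
#' Assigns time-ordered GPS fixes to location clusters of radius `radius_m`
#' (150 m by default): each fix joins the first existing cluster (by creation
#' order) whose running-mean centroid lies within the radius, otherwise it
#' founds a new cluster. The assignment is order-dependent by design; running
#' mean centroids can drift, so cluster membership is guaranteed within the
#' radius at assignment time, not against the final centroid.
#'
#' @param gps Tibble with `lat`, `lon` (and usually `timestamp`), time-ordered.
#' @param radius_m Cluster radius in meters (default 150).
#' @return Input tibble with an integer `cluster` column; the cluster centroid
#'   table is attached as attribute `"centroids"` (tibble with `cluster`,
#'   `centroid_lat`, `centroid_lon`, `n_fixes`).
#' @export
cluster_locations <- function(gps, radius_m = 150) {
  stopifnot(all(c("lat", "lon") %in% names(gps)))
  if (nrow(gps) == 0) {
    out <- dplyr::mutate(gps, cluster = integer(0))
    attr(out, "centroids") <- tibble::tibble(
      cluster = integer(0), centroid_lat = double(0),
      centroid_lon = double(0), n_fixes = integer(0))
    return(out)
  }
  res <- cpp_greedy_cluster(gps$lat, gps$lon, radius_m)
  out <- dplyr::mutate(gps, cluster = res$cluster)
  attr(out, "centroids") <- tibble::tibble(
    cluster = seq_along(res$centroid_lat),
    centroid_lat = res$centroid_lat,
    centroid_lon = res$centroid_lon,
    n_fixes = res$size)
  out
}

#' Normalized location entropy
#'
#' Shannon entropy of the dwell-time share across visited location clusters,
#' normalized by `log(N)` so the value depends only on the shape of the
#' distribution, not on the number of clusters:
#' \deqn{H = -\sum_i p_i \log p_i / \log N}
#' with \eqn{0 \log 0 \equiv 0}. Returns 0 for a single cluster (all dwell in
#' one place) and 1 for a uniform spread over any number of clusters. The
#' logarithm base cancels in the ratio.
#'
#' @param p Numeric vector of dwell-time fractions; nonnegative, summing to 1.
#' @return Normalized entropy in \[0, 1\].
#' @examples
#' normalized_entropy(c(1))           # 0: a single cluster
#' normalized_entropy(rep(0.2, 5))    # 1: uniform over five clusters
#' normalized_entropy(c(0.75, 0.25))
#' @export
normalized_entropy <- function(p) {
  if (any(p < 0)) stop_bad_arg("dwell fractions must be nonnegative")
  if (abs(sum(p) - 1) > 1e-9) stop_bad_arg("dwell fractions must sum to 1 (got %.12f)", sum(p))
  n <- length(p)
  if (n <= 1) return(0)
  pos <- p[p > 0]
  h <- -sum(pos * log(pos))
  val <- h / log(n)
  min(max(val, 0), 1)
}

#' Classify an hour by the number of locations visited
#'
#' Maps the count of distinct location clusters visited for at least the
#' minimum dwell within an hour to a mobility state: 1 location is
#' `"stationary"` (at home, work or school), 2-9 is `"moving"`, 10 or more is
#' `"transportation"`, and 0 (no fix and no carried-forward position) is
#' `"no_data"`. A count of exactly 10 falls in `"transportation"` so the three
#' classes partition the counts contiguously.
#'
#' @param locations_visited Integer vector of per-hour location counts.
#' @return Character vector of states.
#' @export
classify_hour <- function(locations_visited) {
  stopifnot(all(locations_visited >= 0))
  out <- rep("no_data", length(locations_visited))
  out[locations_visited == 1] <- "stationary"
  out[locations_visited >= 2 & locations_visited <= 9] <- "moving"
  out[locations_visited >= 10] <- "transportation"
  out
}

# Hourly cluster-dwell matrix for one local day.
# sec: seconds since local midnight (sorted); cluster: integer ids 1..K.
# Interval [sec_i, sec_{i+1}) belongs to cluster_i; the last fix carries
# forward to local midnight (displacement sampling: no new fix => no movement).
hour_dwell_matrix <- function(sec, cluster) {
  k <- if (length(cluster)) max(cluster) else 0L
  cpp_hour_dwell(sec, as.integer(cluster), as.integer(k))
}

#' Locations visited within an hour
#'
#' Counts the distinct location clusters occupied for at least `min_dwell_s`
#' seconds within a local hour window, with dwell intervals clipped at the
#' hour boundaries. Dwell is attributed to the earlier fix's cluster and the
#' day's final fix carries forward to local midnight.
#'
#' @param sec Seconds since local midnight of the day's fixes, sorted.
#' @param cluster Integer cluster id per fix (from [cluster_locations()]).
#' @param hour Local hour index 0-23.
#' @param min_dwell_s Minimum dwell per cluster to count a visit (default 120).
#' @return Integer count of qualifying clusters (0 when the hour has no data).
#' @export
locations_per_hour <- function(sec, cluster, hour, min_dwell_s = 120) {
  stopifnot(hour %in% 0:23)
  if (length(sec) == 0) return(0L)
  dw <- hour_dwell_matrix(sec, cluster)
  sum(dw[, hour + 1] >= min_dwell_s)
}

# Full mobility summary for one local day's fixes.
# gps: tibble(timestamp, lat, lon) already inside the local day, time-ordered.
daily_mobility_one <- function(sec, lat, lon, radius_m = 150, min_dwell_s = 120,
                               displacement_m = 20) {
  if (length(sec) == 0) {
    return(list(time_sedentary_h = NA_real_, time_moving_h = NA_real_,
                distance_km = NA_real_, entropy_norm = NA_real_,
                hours_observed = 0L, n_clusters = NA_integer_))
  }
  keep <- cpp_displacement_keep(lat, lon, displacement_m)
  sec <- sec[keep]; lat <- lat[keep]; lon <- lon[keep]
  n <- length(sec)
  dist_m <- if (n >= 2) {
    sum(cpp_haversine(lat[-n], lon[-n], lat[-1], lon[-1]))
  } else 0
  cl <- cpp_greedy_cluster(lat, lon, radius_m)
  dw <- hour_dwell_matrix(sec, cl$cluster)
  dwell_by_cluster <- rowSums(dw)
  tot <- sum(dwell_by_cluster)
  entropy <- if (tot > 0) {
    normalized_entropy(dwell_by_cluster / tot)
  } else 0
  visited <- colSums(dw >= min_dwell_s)
  covered <- colSums(dw) > 0
  state <- classify_hour(as.integer(visited))
  # an hour covered only by a long carry-forward interval still has >=2 min
  # dwell in that cluster, so visited >= 1 whenever covered for >= min_dwell
  state[!covered] <- "no_data"
  list(time_sedentary_h = sum(state == "stationary"),
       time_moving_h = sum(state %in% c("moving", "transportation")),
       distance_km = dist_m / 1000,
       entropy_norm = entropy,
       hours_observed = sum(covered),
       n_clusters = length(dwell_by_cluster))
}

#' Daily mobility features from a GPS stream
#'
#' Splits a participant's GPS stream into local days (midnight-to-midnight,
#' half-open, on the participant's clock), applies the displacement filter,
#' clusters each day's fixes into 150 m locations, and summarizes each day:
#' total distance traveled (km, Haversine over retained fixes), normalized
#' location entropy over the day's dwell-time distribution, and hours
#' classified stationary vs moving/transportation from the per-hour count of
#' locations visited for at least 2 minutes. Hours with no fix and no
#' carried-forward position are `no_data` and excluded from `hours_observed`.
#'
#' @param gps Tibble with `timestamp` (POSIXct, UTC), `lat`, `lon`.
#' @param tz_offset_min Participant's UTC offset in minutes (default 0).
#' @param radius_m Location-cluster radius in meters (default 150).
#' @param min_dwell_s Minimum within-hour dwell to count a visit (default 120).
#' @param displacement_m Displacement-sampling threshold in meters (default 20).
#' @return Tibble with one row per local day that has at least one fix:
#'   `date`, `time_sedentary_h`, `time_moving_h`, `distance_km`,
#'   `entropy_norm`, `hours_observed`, `n_clusters`.
#' @export
extract_mobility <- function(gps, tz_offset_min = 0, radius_m = 150,
                             min_dwell_s = 120, displacement_m = 20) {
  if (nrow(gps) == 0) {
    return(tibble::tibble(date = as.Date(character(0)),
                          time_sedentary_h = double(0), time_moving_h = double(0),
                          distance_km = double(0), entropy_norm = double(0),
                          hours_observed = integer(0), n_clusters = integer(0)))
  }
  le <- local_epoch(gps$timestamp, tz_offset_min)
  ord <- order(le)
  le <- le[ord]
  lat <- gps$lat[ord]; lon <- gps$lon[ord]
  day <- floor(le / SECS_DAY)
  sec <- le %% SECS_DAY
  idx <- split(seq_along(le), day)
  nd <- length(idx)
  sed <- mov <- dist <- ent <- numeric(nd)
  hobs <- ncl <- integer(nd)
  for (j in seq_len(nd)) {
    i <- idx[[j]]
    r <- daily_mobility_one(sec[i], lat[i], lon[i], radius_m = radius_m,
                            min_dwell_s = min_dwell_s,
                            displacement_m = displacement_m)
    sed[j] <- r$time_sedentary_h; mov[j] <- r$time_moving_h
    dist[j] <- r$distance_km; ent[j] <- r$entropy_norm
    hobs[j] <- r$hours_observed; ncl[j] <- r$n_clusters
  }
  fast_tibble(date = as.Date(as.numeric(names(idx)), origin = "1970-01-01"),
                 time_sedentary_h = sed, time_moving_h = mov,
                 distance_km = dist, entropy_norm = ent,
                 hours_observed = hobs, n_clusters = ncl)
}
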