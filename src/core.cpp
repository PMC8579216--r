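#include <Rcpp.h>
using namespace Rcpp;

static const double EARTH_R = 6371000.0;
static const double DEG = M_PI / 180.0;

// great-circle distance on a 6371 km sphere, inputs in degrees
static double hav(double lat1, double lon1, double lat2, double lon2) {
  double dphi = (lat2 - lat1) * DEG;
  double dlam = (lon2 - lon1) * DEG;
  double a = std::sin(dphi / 2) * std::sin(dphi / 2) +
             std::cos(lat1 * DEG) * std::cos(lat2 * DEG) *
             std::sin(dlam / 2) * std::sin(dlam / 2);
  if (a > 1.0) a = 1.0;
  return 2.0 * EARTH_R * std::asin(std::sqrt(a));
}

// [[Rcpp::export]]
NumericVector cpp_haversine(NumericVector lat1, NumericVector lon1,
                            NumericVector lat2, NumericVector lon2) {
  R_xlen_t n = lat1.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = hav(lat1[i], lon1[i], lat2[i], lon2[i]);
  return out;
}

// Keep the first fix; keep each later fix iff its distance from the last
// *kept* fix strictly exceeds threshold_m (the app's 20 m sampling rule).
// [[Rcpp::export]]
LogicalVector cpp_displacement_keep(NumericVector lat, NumericVector lon,
                                    double threshold_m) {
  R_xlen_t n = lat.size();
  LogicalVector keep(n);
  if (n == 0) return keep;
  keep[0] = true;
  double klat = lat[0], klon = lon[0];
  for (R_xlen_t i = 1; i < n; ++i) {
    if (hav(klat, klon, lat[i], lon[i]) > threshold_m) {
      keep[i] = true;
      klat = lat[i];
      klon = lon[i];
    }
  }
  return keep;
}

// Greedy sequential clustering: each point joins the first existing cluster
// (by creation order) whose running-mean centroid lies within radius_m, else
// founds a new cluster. Centroids are running means over member coordinates.
// [[Rcpp::export]]
List cpp_greedy_cluster(NumericVector lat, NumericVector lon, double radius_m) {
  R_xlen_t n = lat.size();
  IntegerVector id(n);
  std::vector<double> clat, clon;
  std::vector<int> csize;
  for (R_xlen_t i = 0; i < n; ++i) {
    int found = -1;
    for (size_t k = 0; k < clat.size(); ++k) {
      if (hav(clat[k], clon[k], lat[i], lon[i]) <= radius_m) { found = (int)k; break; }
    }
    if (found < 0) {
      clat.push_back(lat[i]);
      clon.push_back(lon[i]);
      csize.push_back(1);
      id[i] = (int)clat.size();
    } else {
      csize[found] += 1;
      clat[found] += (lat[i] - clat[found]) / csize[found];
      clon[found] += (lon[i] - clon[found]) / csize[found];
      id[i] = found + 1;
    }
  }
  return List::create(_["cluster"] = id,
                      _["centroid_lat"] = NumericVector(clat.begin(), clat.end()),
                      _["centroid_lon"] = NumericVector(clon.begin(), clon.end()),
                      _["size"] = IntegerVector(csize.begin(), csize.end()));
}

// Dwell seconds per (cluster, local hour) over one local day.
// t: seconds since local midnight, sorted, in [0, 86400); cluster: 1..n_clusters.
// Interval [t_i, t_{i+1}) belongs to cluster_i; the final fix carries forward
// to local midnight. Intervals are clipped at hour boundaries.
// [[Rcpp::export]]
NumericMatrix cpp_hour_dwell(NumericVector t, IntegerVector cluster,
                             int n_clusters) {
  R_xlen_t n = t.size();
  NumericMatrix dwell(n_clusters, 24);
  for (R_xlen_t i = 0; i < n; ++i) {
    double a = t[i];
    double b = (i + 1 < n) ? t[i + 1] : 86400.0;
    if (b <= a) continue;
    int cl = cluster[i] - 1;
    int h0 = (int)std::floor(a / 3600.0);
    int h1 = (int)std::floor((b - 1e-9) / 3600.0);
    if (h1 > 23) h1 = 23;
    for (int h = h0; h <= h1; ++h) {
      double lo = std::max(a, 3600.0 * h);
      double hi = std::min(b, 3600.0 * (h + 1));
      if (hi > lo) dwell(cl, h) += hi - lo;
    }
  }
  return dwell;
}
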