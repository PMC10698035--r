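#include <Rcpp.h>
using namespace Rcpp;

// Gaussian profile-likelihood pieces for a unit-variance stationary Toeplitz
// covariance R built from autocorrelations r[0..n-1] (r[0] = 1).
// One Levinson-Durbin sweep yields, in O(n^2):
//   logdet  = log|R|
//   qxx     = x' R^-1 x
//   qoo     = 1' R^-1 1
//   qxo     = 1' R^-1 x
// via one-step prediction errors e_t and innovation variances v_t:
//   x'R^-1 x = sum_t e_t(x)^2 / v_{t-1},  log|R| = sum_t log v_{t-1}.
// The prediction error of the all-ones vector is 1 - sum(phi), tracked
// incrementally.
// All inner loops are forward-aligned (a reversed copy `phir` of the AR
// coefficients is maintained) so the compiler can vectorize them.
// [[Rcpp::export(name = ".fgn_quadforms")]]
List fgn_quadforms(NumericVector r, NumericVector x) {
  int n = x.size();
  if (r.size() < n) stop("autocorrelation vector shorter than series");
  std::vector<double> phi(n, 0.0), phir(n, 0.0);
  const double* rp = REAL(r);
  const double* xp = REAL(x);
  double v = 1.0;
  double logdet = 0.0;              // v_0 = 1 contributes log 1
  double qxx = xp[0] * xp[0];
  double qoo = 1.0;
  double qxo = xp[0];
  double s = 0.0;                   // sum of phi at current order
  for (int k = 1; k < n; ++k) {
    // phir[i] = phi[k - i] (order k-1 coefficients, reversed)
    double accr = 0.0, ax = 0.0, cx = 0.0;
    for (int i = 1; i < k; ++i) {
      accr += phir[i] * rp[i];
      ax += phir[i] * xp[i];        // = sum_j phi[j] x[k-j]
      cx += phi[i] * xp[i];
    }
    double kref = (rp[k] - accr) / v;
    if (!std::isfinite(kref)) stop("Levinson recursion diverged");
    for (int j = 1; j < k; ++j) phi[j] -= kref * phir[j];
    phi[k] = kref;
    s = s * (1.0 - kref) + kref;
    v *= (1.0 - kref * kref);
    if (v <= 0) stop("innovation variance underflow (H too close to 1?)");
    // one-step prediction error of x[k] under the order-k coefficients,
    // assembled from the order-(k-1) accumulators
    double ex = xp[k] - (ax - kref * cx + kref * xp[0]);
    double eo = 1.0 - s;
    logdet += std::log(v);
    qxx += ex * ex / v;
    qoo += eo * eo / v;
    qxo += ex * eo / v;
    // refresh the reversed copy for the next order
    for (int i = 1; i <= k; ++i) phir[i] = phi[k + 1 - i];
  }
  return List::create(_["logdet"] = logdet, _["qxx"] = qxx,
                      _["qoo"] = qoo, _["qxo"] = qxo);
}

static inline double sqdist(const NumericMatrix& X, int i, int j) {
  double d = 0.0;
  for (int c = 0; c < X.ncol(); ++c) {
    double u = X(i, c) - X(j, c);
    d += u * u;
  }
  return d;
}

// Nearest neighbor of every row, excluding temporal neighbors within
// +/- theiler samples. Returns 1-based indices and distances.
// [[Rcpp::export(name = ".nn_all")]]
List nn_all(NumericMatrix X, int theiler) {
  int n = X.nrow();
  IntegerVector idx(n, NA_INTEGER);
  NumericVector dist(n, NA_REAL);
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    int bj = -1;
    for (int j = 0; j < n; ++j) {
      if (std::abs(i - j) <= theiler) continue;
      double d = sqdist(X, i, j);
      if (d < best) { best = d; bj = j; }
    }
    if (bj >= 0) { idx[i] = bj + 1; dist[i] = std::sqrt(best); }
  }
  return List::create(_["index"] = idx, _["dist"] = dist);
}

// Neighbor search for Wolf's algorithm: find the point j (with |j - i| >
// theiler, j <= jmax) whose distance to row i lies in [dmin, dmax] and whose
// angular deviation from the current separation vector `dir` is smallest,
// subject to angle <= max_angle (degrees). Falls back to the closest point in
// the distance band ignoring the angle, then to the closest point beyond dmin.
// [[Rcpp::export(name = ".wolf_neighbor")]]
List wolf_neighbor(NumericMatrix X, int i1, NumericVector dir, int theiler,
                   double dmin, double dmax, double max_angle, int jmax1) {
  int n = X.nrow(), m = X.ncol();
  int i = i1 - 1;
  int jmax = std::min(jmax1, n);
  double dirn = 0.0;
  for (int c = 0; c < m; ++c) dirn += dir[c] * dir[c];
  dirn = std::sqrt(dirn);
  double cos_lim = std::cos(max_angle * M_PI / 180.0);
  int best_ang_j = -1, best_band_j = -1, best_any_j = -1;
  double best_cos = -2.0, best_band_d = R_PosInf, best_any_d = R_PosInf;
  // strict-improvement margins keep the selection stable under relative
  // perturbations of the coordinates at rounding level (so the exponent is
  // numerically invariant to trajectory translation and scaling)
  const double rel = 1.0 - 1e-9;
  for (int j = 0; j < jmax; ++j) {
    if (std::abs(i - j) <= theiler) continue;
    double d = std::sqrt(sqdist(X, i, j));
    if (d <= dmin) continue;
    if (d < best_any_d * rel) { best_any_d = d; best_any_j = j; }
    if (d > dmax) continue;
    if (d < best_band_d * rel) { best_band_d = d; best_band_j = j; }
    if (dirn > 0) {
      double dot = 0.0;
      for (int c = 0; c < m; ++c) dot += (X(j, c) - X(i, c)) * dir[c];
      double cs = dot / (d * dirn);
      if (cs >= cos_lim && cs > best_cos + 1e-9) { best_cos = cs; best_ang_j = j; }
    }
  }
  // tier 1: angle criterion met; tier 2: in distance band, angle relaxed;
  // tier 3: nearest beyond the noise floor
  int tier = best_ang_j >= 0 ? 1 : (best_band_j >= 0 ? 2 : 3);
  int j = best_ang_j >= 0 ? best_ang_j : (best_band_j >= 0 ? best_band_j : best_any_j);
  if (j < 0) return List::create(_["index"] = NA_INTEGER, _["dist"] = NA_REAL,
                                 _["tier"] = NA_INTEGER);
  double d = std::sqrt(sqdist(X, i, j));
  return List::create(_["index"] = j + 1, _["dist"] = d, _["tier"] = tier);
}
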