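#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Natural cubic spline through knots (xk, yk), evaluated at t = 0..n-1.
// Knots must be strictly increasing; with the mirrored boundary knots added
// by build_knots() they bracket [0, n-1], so no extrapolation occurs in
// practice (the first/last polynomial extends otherwise).
static void spline_eval(const std::vector<double> &xk,
                        const std::vector<double> &yk,
                        const int n, double *out) {
  const int m = (int)xk.size();
  if (m < 2) {
    const double v = (m == 1) ? yk[0] : 0.0;
    for (int i = 0; i < n; ++i) out[i] = v;
    return;
  }
  if (m == 2) {
    const double slope = (yk[1] - yk[0]) / (xk[1] - xk[0]);
    for (int i = 0; i < n; ++i) out[i] = yk[0] + slope * ((double)i - xk[0]);
    return;
  }
  std::vector<double> h(m - 1), mu(m, 0.0), z(m, 0.0), c(m, 0.0);
  for (int i = 0; i < m - 1; ++i) h[i] = xk[i + 1] - xk[i];
  for (int i = 1; i < m - 1; ++i) {
    const double alpha =
        3.0 * ((yk[i + 1] - yk[i]) / h[i] - (yk[i] - yk[i - 1]) / h[i - 1]);
    const double l = 2.0 * (xk[i + 1] - xk[i - 1]) - h[i - 1] * mu[i - 1];
    mu[i] = h[i] / l;
    z[i] = (alpha - h[i - 1] * z[i - 1]) / l;
  }
  for (int j = m - 2; j >= 1; --j) c[j] = z[j] - mu[j] * c[j + 1];
  int j = 0;
  for (int i = 0; i < n; ++i) {
    const double x = (double)i;
    while (j < m - 2 && x > xk[j + 1]) ++j;
    const double dt = x - xk[j];
    const double b =
        (yk[j + 1] - yk[j]) / h[j] - h[j] * (c[j + 1] + 2.0 * c[j]) / 3.0;
    const double d = (c[j + 1] - c[j]) / (3.0 * h[j]);
    out[i] = yk[j] + dt * (b + dt * (c[j] + dt * d));
  }
}

// Strict local extrema of the projected signal (plateau onsets count once).
static void find_extrema(const std::vector<double> &p,
                         std::vector<int> &mx, std::vector<int> &mn) {
  const int n = (int)p.size();
  mx.clear();
  mn.clear();
  for (int i = 1; i < n - 1; ++i) {
    if (p[i] > p[i - 1] && p[i] >= p[i + 1]) mx.push_back(i);
    else if (p[i] < p[i - 1] && p[i] <= p[i + 1]) mn.push_back(i);
  }
}

// Envelope knots for channel c: signal values at projection-extrema sample
// indices, extended by mirroring up to two extrema about each end so the
// spline is supported on the full [0, n-1] range.
static void build_knots(const std::vector<int> &e, const NumericMatrix &X,
                        const int c, const int n,
                        std::vector<double> &xk, std::vector<double> &yk) {
  const int m = (int)e.size();
  xk.clear();
  yk.clear();
  const int nm = std::min(2, m);
  for (int i = nm - 1; i >= 0; --i) {
    if (e[i] > 0) {
      xk.push_back(-(double)e[i]);
      yk.push_back(X(e[i], c));
    }
  }
  for (int i = 0; i < m; ++i) {
    xk.push_back((double)e[i]);
    yk.push_back(X(e[i], c));
  }
  for (int i = 0; i < nm; ++i) {
    const int idx = m - 1 - i;
    if (e[idx] < n - 1) {
      xk.push_back(2.0 * (n - 1) - (double)e[idx]);
      yk.push_back(X(e[idx], c));
    }
  }
}

// One multivariate sifting ingredient: the mean of direction-wise upper/lower
// envelope midlines. X is n x d (samples x channels); D is d x ndir with unit
// columns. A direction contributes only if its projection has at least two
// maxima and two minima. Returns the mean envelope, the number of usable
// directions, and per-direction extrema counts.
// [[Rcpp::export(name = ".memd_mean_envelope")]]
List memd_mean_envelope(const NumericMatrix &X, const NumericMatrix &D) {
  const int n = X.nrow(), d = X.ncol(), nd = D.ncol();
  NumericMatrix env(n, d);
  IntegerVector next(nd);
  int usable = 0;
  std::vector<double> p(n), up(n), lo(n), xk, yk;
  std::vector<int> mx, mn;
  xk.reserve(n);
  yk.reserve(n);
  for (int k = 0; k < nd; ++k) {
    for (int i = 0; i < n; ++i) {
      double s = 0.0;
      for (int c = 0; c < d; ++c) s += X(i, c) * D(c, k);
      p[i] = s;
    }
    find_extrema(p, mx, mn);
    next[k] = (int)(mx.size() + mn.size());
    if ((int)mx.size() < 2 || (int)mn.size() < 2) continue;
    ++usable;
    for (int c = 0; c < d; ++c) {
      build_knots(mx, X, c, n, xk, yk);
      spline_eval(xk, yk, n, up.data());
      build_knots(mn, X, c, n, xk, yk);
      spline_eval(xk, yk, n, lo.data());
      for (int i = 0; i < n; ++i) env(i, c) += 0.5 * (up[i] + lo[i]);
    }
  }
  if (usable > 0) {
    for (int c = 0; c < d; ++c)
      for (int i = 0; i < n; ++i) env(i, c) /= usable;
  }
  return List::create(_["env"] = env, _["n_usable"] = usable,
                      _["n_extrema"] = next);
}
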