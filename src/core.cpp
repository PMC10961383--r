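#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

static const double TWOPI = 2.0 * M_PI;

static inline double wrap_rad(double x) {
  // wrap into [-pi, pi)
  double y = x + M_PI;
  y -= TWOPI * std::floor(y / TWOPI);
  return y - M_PI;
}

//' Square median filter with replicate edge padding
//'
//' @param x numeric matrix
//' @param k odd window side length in pixels
//' @return filtered matrix of the same dimensions
//' @keywords internal
// [[Rcpp::export]]
NumericMatrix median_filter_cpp(NumericMatrix x, int k) {
  if (k < 1 || k % 2 == 0) stop("kernel size must be a positive odd integer");
  int n = x.nrow(), m = x.ncol(), h = k / 2;
  NumericMatrix out(n, m);
  std::vector<double> buf(static_cast<size_t>(k) * k);
  for (int j = 0; j < m; ++j) {
    for (int i = 0; i < n; ++i) {
      size_t c = 0;
      for (int dj = -h; dj <= h; ++dj) {
        int jj = std::min(std::max(j + dj, 0), m - 1);
        for (int di = -h; di <= h; ++di) {
          int ii = std::min(std::max(i + di, 0), n - 1);
          buf[c++] = x(ii, jj);
        }
      }
      std::nth_element(buf.begin(), buf.begin() + c / 2, buf.begin() + c);
      out(i, j) = buf[c / 2];
    }
  }
  return out;
}

// Reliability-sorted region-growing 2-D phase unwrapper.
//
// Pixel reliability follows the second-difference measure: for each interior
// pixel the horizontal, vertical and two diagonal wrapped second differences
// are combined as D = sqrt(H^2 + V^2 + D1^2 + D2^2); small D means reliable.
// Edges between 4-neighbours are sorted by the sum of their two pixel D
// values and processed most-reliable first, merging groups of pixels with a
// single 2*pi multiple applied to the smaller group (linked-list groups, so
// the total walk cost is O(N log N)). Residue-carrying inputs still return;
// errors are then distributed along the least reliable edges.

//' @keywords internal
// [[Rcpp::export]]
NumericMatrix unwrap_herraez_cpp(NumericMatrix wrapped) {
  const int n = wrapped.nrow(), m = wrapped.ncol();
  const int N = n * m;
  NumericMatrix out(n, m);
  std::vector<double> val(N);
  for (int j = 0; j < m; ++j)
    for (int i = 0; i < n; ++i)
      val[i + j * n] = wrapped(i, j);

  // pixel unreliability D (border pixels pushed to the very end)
  std::vector<double> D(N, 1e10);
  for (int j = 1; j < m - 1; ++j) {
    for (int i = 1; i < n - 1; ++i) {
      int p = i + j * n;
      double v = val[p];
      double H  = wrap_rad(val[p - 1] - v) - wrap_rad(v - val[p + 1]);
      double V  = wrap_rad(val[p - n] - v) - wrap_rad(v - val[p + n]);
      double D1 = wrap_rad(val[p - n - 1] - v) - wrap_rad(v - val[p + n + 1]);
      double D2 = wrap_rad(val[p + n - 1] - v) - wrap_rad(v - val[p - n + 1]);
      D[p] = std::sqrt(H * H + V * V + D1 * D1 + D2 * D2);
    }
  }

  // edges between vertical and horizontal 4-neighbours
  const int nEdges = (n - 1) * m + n * (m - 1);
  std::vector<int> ea(nEdges), eb(nEdges);
  std::vector<double> er(nEdges);
  int e = 0;
  for (int j = 0; j < m; ++j)
    for (int i = 0; i < n - 1; ++i) {
      int p = i + j * n;
      ea[e] = p; eb[e] = p + 1; er[e] = D[p] + D[p + 1]; ++e;
    }
  for (int j = 0; j < m - 1; ++j)
    for (int i = 0; i < n; ++i) {
      int p = i + j * n;
      ea[e] = p; eb[e] = p + n; er[e] = D[p] + D[p + n]; ++e;
    }
  std::vector<int> ord(nEdges);
  for (int k = 0; k < nEdges; ++k) ord[k] = k;
  std::stable_sort(ord.begin(), ord.end(),
                   [&](int a, int b) { return er[a] < er[b]; });

  // linked-list groups: grp[p] = representative, nxt chains members,
  // tail/size valid at representatives only
  std::vector<int> grp(N), nxt(N, -1), tail(N), sz(N, 1);
  for (int p = 0; p < N; ++p) { grp[p] = p; tail[p] = p; }

  for (int k = 0; k < nEdges; ++k) {
    int a = ea[ord[k]], b = eb[ord[k]];
    int ga = grp[a], gb = grp[b];
    if (ga == gb) continue;
    // shift applied to b's group so that val[b] lands within pi of val[a]
    double shift = TWOPI * std::llround((val[a] - val[b]) / TWOPI);
    if (sz[ga] >= sz[gb]) {
      for (int x = gb; x != -1; x = nxt[x]) { val[x] += shift; grp[x] = ga; }
      nxt[tail[ga]] = gb; tail[ga] = tail[gb]; sz[ga] += sz[gb];
    } else {
      for (int x = ga; x != -1; x = nxt[x]) { val[x] -= shift; grp[x] = gb; }
      nxt[tail[gb]] = ga; tail[gb] = tail[ga]; sz[gb] += sz[ga];
    }
  }

  for (int j = 0; j < m; ++j)
    for (int i = 0; i < n; ++i)
      out(i, j) = val[i + j * n];
  return out;
}
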