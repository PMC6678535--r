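#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Circular-binary-segmentation arc scan.
//
// For a probe series x[0..n-1] the candidate change is an arc (i, j]
// (boundaries i < j, arc length k = j - i) compared against the rest of the
// segment. With centered prefix sums C[t] = sum_{u<t} x[u] - t * mean(x),
// the two-sample t-like statistic (common SD factored out; it cancels in
// both the argmax and the permutation comparison) is
//   T(i, j) = |C[j] - C[i]| * sqrt(n / (k * (n - k))).
// For long segments the scan is windowed (overlapping windows, each scanned
// exhaustively); within a window the same formula applies with n replaced
// by the window length.

namespace {

struct Window { R_xlen_t start; R_xlen_t len; };

std::vector<Window> make_windows(R_xlen_t n, int window, int max_exhaustive) {
  std::vector<Window> out;
  if (n <= max_exhaustive || n <= window) {
    out.push_back({0, n});
    return out;
  }
  R_xlen_t step = window / 2;
  R_xlen_t s = 0;
  while (s + window < n) {
    out.push_back({s, (R_xlen_t)window});
    s += step;
  }
  out.push_back({n - window, (R_xlen_t)window});
  return out;
}

// centered prefix sums for x[a .. a+m)
void centered_prefix(const double* x, R_xlen_t a, R_xlen_t m,
                     std::vector<double>& C) {
  C.resize(m + 1);
  double s = 0.0;
  for (R_xlen_t t = 0; t < m; ++t) s += x[a + t];
  const double mu = s / m;
  C[0] = 0.0;
  double acc = 0.0;
  for (R_xlen_t t = 0; t < m; ++t) {
    acc += x[a + t] - mu;
    C[t + 1] = acc;
  }
}

} // namespace

// [[Rcpp::export(name = ".cpp_cbs_scan")]]
List cpp_cbs_scan(NumericVector z, int min_width, int window,
                  int max_exhaustive) {
  const R_xlen_t n = z.size();
  if (n < 2 * min_width) {
    return List::create(_["i"] = -1, _["j"] = -1, _["stat"] = R_NegInf);
  }
  const double* x = REAL(z);
  std::vector<Window> wins = make_windows(n, window, max_exhaustive);
  double best = R_NegInf;
  R_xlen_t bi = -1, bj = -1;
  std::vector<double> C;
  std::vector<double> w;
  for (const Window& win : wins) {
    const R_xlen_t m = win.len;
    if (m < 2 * min_width) continue;
    centered_prefix(x, win.start, m, C);
    w.assign(m + 1, 0.0);
    for (R_xlen_t k = min_width; k <= m - min_width; ++k) {
      w[k] = std::sqrt((double)m / ((double)k * (double)(m - k)));
    }
    for (R_xlen_t i = 0; i + min_width <= m; ++i) {
      const double Ci = C[i];
      const R_xlen_t jmax = std::min(m, i + (m - min_width));
      for (R_xlen_t j = i + min_width; j <= jmax; ++j) {
        const double stat = std::fabs(C[j] - Ci) * w[j - i];
        if (stat > best) {
          best = stat;
          bi = win.start + i;
          bj = win.start + j;
        }
      }
    }
  }
  return List::create(_["i"] = (double)bi, _["j"] = (double)bj,
                      _["stat"] = best);
}

// Exact early-exit check: does the max arc statistic of z reach `thresh`?
// Equivalent to cpp_cbs_scan(z)$stat >= thresh, but prunes arc widths k
// whose best possible statistic, (max C - min C) * w_k, cannot reach the
// threshold. w_k decreases towards k = m/2, so once the bound fails at
// width kk it fails for every remaining width (widths are visited in
// decreasing-w order: kk and m - kk together). Under permutation-null data
// with a large observed threshold this prunes almost the whole scan.
// [[Rcpp::export(name = ".cpp_cbs_exceeds")]]
bool cpp_cbs_exceeds(NumericVector z, double thresh, int min_width,
                     int window, int max_exhaustive) {
  const R_xlen_t n = z.size();
  if (n < 2 * min_width) return false;
  const double* x = REAL(z);
  std::vector<Window> wins = make_windows(n, window, max_exhaustive);
  std::vector<double> C;
  for (const Window& win : wins) {
    const R_xlen_t m = win.len;
    if (m < 2 * min_width) continue;
    centered_prefix(x, win.start, m, C);
    double cmin = C[0], cmax = C[0];
    for (R_xlen_t t = 1; t <= m; ++t) {
      if (C[t] < cmin) cmin = C[t];
      if (C[t] > cmax) cmax = C[t];
    }
    const double range = cmax - cmin;
    for (R_xlen_t kk = min_width; 2 * kk <= m; ++kk) {
      const double wk =
          std::sqrt((double)m / ((double)kk * (double)(m - kk)));
      if (range * wk < thresh) break;
      const double cut = thresh / wk;
      // width kk
      for (R_xlen_t i = 0; i + kk <= m; ++i) {
        if (std::fabs(C[i + kk] - C[i]) >= cut) return true;
      }
      // mirrored width m - kk (same weight), skip duplicate when m == 2*kk
      const R_xlen_t k2 = m - kk;
      if (k2 != kk && k2 <= m - min_width) {
        for (R_xlen_t i = 0; i + k2 <= m; ++i) {
          if (std::fabs(C[i + k2] - C[i]) >= cut) return true;
        }
      }
    }
  }
  return false;
}
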