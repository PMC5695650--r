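#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Direct-form I IIR filter with zero initial conditions; a[0] must be 1.
// [[Rcpp::export]]
NumericVector iirFilterCpp(NumericVector b, NumericVector a,
                           NumericVector x) {
  const int n = x.size(), nb = b.size(), na = a.size();
  NumericVector y(n);
  const double* xp = x.begin();
  const double* bp = b.begin();
  const double* ap = a.begin();
  double* yp = y.begin();
  const int warm = std::min(n, std::max(nb, na));
  for (int i = 0; i < warm; ++i) {
    double acc = 0.0;
    const int jb = std::min(nb - 1, i);
    for (int j = 0; j <= jb; ++j) acc += bp[j] * xp[i - j];
    const int ja = std::min(na - 1, i);
    for (int j = 1; j <= ja; ++j) acc -= ap[j] * yp[i - j];
    yp[i] = acc;
  }
  for (int i = warm; i < n; ++i) {
    double acc = 0.0;
    for (int j = 0; j < nb; ++j) acc += bp[j] * xp[i - j];
    for (int j = 1; j < na; ++j) acc -= ap[j] * yp[i - j];
    yp[i] = acc;
  }
  return y;
}

// Centered moving SD with shrinking edge windows (half-width h), O(n).
// [[Rcpp::export]]
NumericVector rollingSDCpp(NumericVector x, int h) {
  const int n = x.size();
  NumericVector out(n);
  const double* xp = x.begin();
  double* op = out.begin();
  std::vector<double> cs(n + 1), cs2(n + 1);
  cs[0] = 0.0; cs2[0] = 0.0;
  double a = 0.0, b = 0.0;
  for (int i = 0; i < n; ++i) {
    a += xp[i];
    b += xp[i] * xp[i];
    cs[i + 1] = a;
    cs2[i + 1] = b;
  }
  const double* c1 = cs.data();
  const double* c2 = cs2.data();
  for (int i = 0; i < n; ++i) {
    const int lo = i - h > 0 ? i - h : 0;
    const int hi = i + h < n - 1 ? i + h : n - 1;
    const double m = hi - lo + 1;
    const double s1 = c1[hi + 1] - c1[lo];
    const double s2 = c2[hi + 1] - c2[lo];
    const double v = (s2 - s1 * s1 / m) / (m - 1);
    op[i] = v > 0 ? std::sqrt(v) : 0.0;
  }
  return out;
}

static double medianOf(std::vector<double>& v) {
  const size_t m = v.size();
  if (m == 0) return NA_REAL;
  const size_t h = m / 2;
  std::nth_element(v.begin(), v.begin() + h, v.end());
  double hi = v[h];
  if (m % 2 == 1) return hi;
  std::nth_element(v.begin(), v.begin() + h - 1, v.begin() + h);
  return 0.5 * (v[h - 1] + hi);
}

// Row-wise medians with NA removal (all-NA rows give NA).
// [[Rcpp::export]]
NumericVector rowMediansCpp(NumericMatrix m) {
  const int nr = m.nrow(), nc = m.ncol();
  NumericVector out(nr);
  std::vector<double> buf;
  buf.reserve(nc);
  for (int i = 0; i < nr; ++i) {
    buf.clear();
    for (int j = 0; j < nc; ++j) {
      const double v = m(i, j);
      if (!ISNAN(v)) buf.push_back(v);
    }
    out[i] = medianOf(buf);
  }
  return out;
}
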