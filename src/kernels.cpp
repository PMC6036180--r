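#include <Rcpp.h>
using namespace Rcpp;

// Sliding-window peak-to-peak amplitude. Windows of length w advance by
// step samples; a trailing partial window is discarded.
// [[Rcpp::export]]
NumericVector cpp_sliding_ptp(NumericVector x, int w, int step) {
  int n = x.size();
  if (w <= 0 || step <= 0 || n < w) stop("window does not fit signal");
  int k = (n - w) / step + 1;
  NumericVector out(k);
  for (int j = 0; j < k; ++j) {
    int s = j * step;
    double lo = x[s], hi = x[s];
    for (int i = s + 1; i < s + w; ++i) {
      double v = x[i];
      if (v < lo) lo = v;
      if (v > hi) hi = v;
    }
    out[j] = hi - lo;
  }
  return out;
}

// Higuchi curve lengths L(k) for k = 1..kmax, averaged over the k offset
// series. Normalisation follows the standard algorithm:
//   L_m(k) = [ sum_i |x(m+ik) - x(m+(i-1)k)| * (N-1) / (floor((N-m)/k) * k) ] / k
// [[Rcpp::export]]
NumericVector cpp_higuchi_lengths(NumericVector x, int kmax) {
  int n = x.size();
  if (kmax < 1 || n < kmax + 1) stop("series too short for kmax");
  NumericVector L(kmax);
  for (int k = 1; k <= kmax; ++k) {
    double acc = 0.0;
    int nm = 0;
    for (int m = 0; m < k; ++m) {
      int nd = (n - 1 - m) / k;  // number of increments in offset series
      if (nd < 1) continue;
      double s = 0.0;
      for (int i = 1; i <= nd; ++i)
        s += std::fabs(x[m + i * k] - x[m + (i - 1) * k]);
      acc += s * double(n - 1) / (double(nd) * k) / k;
      ++nm;
    }
    L[k - 1] = nm > 0 ? acc / nm : 0.0;
  }
  return L;
}

// Amplitude statistics of a band-filtered segment and its envelope:
// total power (mean square), population sd, standardised skewness, raw
// kurtosis, envelope mean and population sd. A degenerate (constant)
// signal is flagged in the 7th slot; skewness/kurtosis are 0 there.
// [[Rcpp::export]]
NumericVector cpp_amp_stats(NumericVector x, NumericVector env) {
  int n = x.size(), ne = env.size();
  double sx = 0, sp = 0, se = 0;
  for (int i = 0; i < n; ++i) { sx += x[i]; sp += x[i] * x[i]; }
  for (int i = 0; i < ne; ++i) se += env[i];
  double mx = sx / n, me = se / ne;
  double m2 = 0, m3 = 0, m4 = 0, e2 = 0;
  for (int i = 0; i < n; ++i) {
    double d = x[i] - mx, d2 = d * d;
    m2 += d2; m3 += d2 * d; m4 += d2 * d2;
  }
  for (int i = 0; i < ne; ++i) { double d = env[i] - me; e2 += d * d; }
  m2 /= n; m3 /= n; m4 /= n; e2 /= ne;
  NumericVector out(7);
  out[0] = sp / n;
  double thr = std::numeric_limits<double>::epsilon() *
    std::max(1.0, mx * mx);
  if (m2 <= thr) {
    out[1] = out[2] = out[3] = 0; out[6] = 1;
  } else {
    out[1] = std::sqrt(m2);
    out[2] = m3 / std::pow(m2, 1.5);
    out[3] = m4 / (m2 * m2);
    out[6] = 0;
  }
  out[4] = me;
  out[5] = std::sqrt(e2);
  return out;
}

// Ranks with average ties (matching rank(x, ties.method = "average")).
// [[Rcpp::export]]
NumericVector cpp_rank_avg(NumericVector x) {
  int n = x.size();
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  std::sort(idx.begin(), idx.end(),
            [&](int a, int b) { return x[a] < x[b]; });
  NumericVector out(n);
  int i = 0;
  while (i < n) {
    int j = i;
    while (j + 1 < n && x[idx[j + 1]] == x[idx[i]]) ++j;
    double r = 0.5 * (i + j) + 1.0;  // average rank of the tie block
    for (int k = i; k <= j; ++k) out[idx[k]] = r;
    i = j + 1;
  }
  return out;
}

// Pearson correlation between x and a lagged copy of y over their overlap,
// for every integer lag in [-maxlag, maxlag]. At lag L > 0, x[t] is paired
// with y[t - L] (y shifted later / leading x). Returns a vector of
// correlations ordered from lag = -maxlag to +maxlag; overlap segments with
// zero variance yield NA.
// [[Rcpp::export]]
NumericVector cpp_lagged_pearson(NumericVector x, NumericVector y, int maxlag) {
  int n = x.size();
  if (y.size() != n) stop("length mismatch");
  if (maxlag < 0 || maxlag >= n - 1) stop("maxlag out of range");
  NumericVector out(2 * maxlag + 1);
  // prefix sums give the per-overlap means/variances in O(1) per lag;
  // only the cross term needs a pass over the overlap
  std::vector<double> cx(n + 1, 0.0), cy(n + 1, 0.0),
                      cxx(n + 1, 0.0), cyy(n + 1, 0.0);
  for (int i = 0; i < n; ++i) {
    cx[i + 1] = cx[i] + x[i];
    cy[i + 1] = cy[i] + y[i];
    cxx[i + 1] = cxx[i] + x[i] * x[i];
    cyy[i + 1] = cyy[i] + y[i] * y[i];
  }
  for (int L = -maxlag; L <= maxlag; ++L) {
    int xs = L > 0 ? L : 0;     // x start index
    int ys = L > 0 ? 0 : -L;    // y start index
    int m = n - std::abs(L);
    double sx = cx[xs + m] - cx[xs], sxx = cxx[xs + m] - cxx[xs];
    double sy = cy[ys + m] - cy[ys], syy = cyy[ys + m] - cyy[ys];
    double sxy = 0;
    const double *xp = &x[xs], *yp = &y[ys];
    for (int i = 0; i < m; ++i) sxy += xp[i] * yp[i];
    double vx = sxx - sx * sx / m, vy = syy - sy * sy / m;
    double cv = sxy - sx * sy / m;
    out[L + maxlag] = (vx > 0 && vy > 0) ? cv / std::sqrt(vx * vy) : NA_REAL;
  }
  return out;
}
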