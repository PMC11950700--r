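#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Maximal information coefficient, characteristic-matrix approximation.
// One axis is equipartitioned into q rows (ties kept together); the other
// axis is optimized by dynamic programming over clump boundaries (clumps:
// maximal x-runs of points sharing a row; equal-x points never split).
// Grid sizes are bounded by p*q <= B(n) = n^alpha; clumps are capped at
// c*p superclumps before the DP. Both orientations are scanned, so the
// statistic is exactly symmetric in its arguments.

namespace {

// Assign q roughly-equal rows to points in sorted-y order; tied y values
// share a row. Returns number of rows actually used.
int equipartition(const std::vector<double> &ysort, int q,
                  std::vector<int> &row) {
  const int n = static_cast<int>(ysort.size());
  row.assign(n, 0);
  double rowsize = static_cast<double>(n) / q;
  int i = 0, curr = 0, h = 0;
  while (i < n) {
    int j = 1;
    while (i + j < n && ysort[i + j] == ysort[i]) ++j;
    if (h != 0 &&
        std::fabs(h + j - rowsize) > std::fabs(h - rowsize) &&
        curr + 1 < q) {
      ++curr;
      h = 0;
      rowsize = static_cast<double>(n - i) / (q - curr);
    }
    for (int t = 0; t < j; ++t) row[i + t] = curr;
    h += j;
    i += j;
  }
  return curr + 1;
}

// Clump endpoints (cumulative point counts) for points given in x order
// with row labels; equal-x runs are atomic, mixed-row runs never merge.
void clump_endpoints(const std::vector<double> &xsort,
                     const std::vector<int> &row,
                     std::vector<int> &ends) {
  const int n = static_cast<int>(xsort.size());
  std::vector<int> label(n);
  int i = 0, neg = -1;
  while (i < n) {
    int j = 1;
    while (i + j < n && xsort[i + j] == xsort[i]) ++j;
    bool mixed = false;
    for (int t = 1; t < j; ++t)
      if (row[i + t] != row[i]) { mixed = true; break; }
    int lab = mixed ? neg-- : row[i];  // distinct negatives never merge
    for (int t = 0; t < j; ++t) label[i + t] = lab;
    i += j;
  }
  ends.clear();
  for (int t = 1; t < n; ++t)
    if (label[t] != label[t - 1]) ends.push_back(t);
  ends.push_back(n);
}

// Reduce clumps to at most khat superclumps, balancing point mass.
void superclumps(const std::vector<int> &ends, int n, int khat,
                 std::vector<int> &out) {
  const int k = static_cast<int>(ends.size());
  if (k <= khat) { out = ends; return; }
  out.clear();
  double size = static_cast<double>(n) / khat;
  int h = 0, prev = 0, used = 0;
  for (int t = 0; t < k; ++t) {
    int m = ends[t] - prev;
    if (h != 0 && std::fabs(h + m - size) > std::fabs(h - size) &&
        used + 1 < khat) {
      out.push_back(prev);
      ++used;
      h = 0;
      size = static_cast<double>(n - prev) / (khat - used);
    }
    h += m;
    prev = ends[t];
  }
  out.push_back(n);
}

inline double xlogx(double m) { return m > 0.0 ? m * std::log(m) : 0.0; }

// Best mutual information over x-partitions with 2..lmax bins, given rows.
// score[l-2] = max_P I(P;Q) for exactly <= l bins (monotone in l).
void optimize_axis(const std::vector<int> &ends,
                   const std::vector<int> &row, int q, int lmax,
                   double hq, int n, std::vector<double> &score) {
  const int k = static_cast<int>(ends.size());
  // cumulative per-row counts at each clump endpoint (k+1 x q), prefix 0 first
  std::vector<double> cum((k + 1) * q, 0.0);
  {
    int idx = 0;
    std::vector<double> acc(q, 0.0);
    for (int t = 0; t < k; ++t) {
      for (; idx < ends[t]; ++idx) acc[row[idx]] += 1.0;
      for (int b = 0; b < q; ++b) cum[(t + 1) * q + b] = acc[b];
    }
  }
  // bin spanning clumps s+1..t contributes sum_b m_b log(m_b/M)
  auto bin_term = [&](int s, int t) {
    double M = 0.0, v = 0.0;
    for (int b = 0; b < q; ++b) {
      double m = cum[t * q + b] - cum[s * q + b];
      v += xlogx(m);
      M += m;
    }
    return v - xlogx(M);
  };
  const double NEG = -1e300;
  // S[t] for current l; prefix t uses clumps 1..t (endpoint index t)
  std::vector<double> Sprev(k + 1, NEG), Scur(k + 1, NEG);
  for (int t = 1; t <= k; ++t) Sprev[t] = bin_term(0, t);  // l = 1
  score.assign(std::max(lmax - 1, 0), NEG);
  for (int l = 2; l <= lmax; ++l) {
    for (int t = 1; t <= k; ++t) {
      double best = NEG;
      for (int s = l - 1; s < t; ++s) {
        if (Sprev[s] <= NEG) continue;
        double v = Sprev[s] + bin_term(s, t);
        if (v > best) best = v;
      }
      Scur[t] = (t >= l) ? best : Sprev[t];  // fewer clumps than bins: reuse
    }
    score[l - 2] = hq + Scur[k] / n;  // = H(Q) - H(Q|P)
    std::swap(Sprev, Scur);
  }
}

double mic_one_orientation(const std::vector<double> &x,
                           const std::vector<double> &y,
                           double B, int cfac) {
  const int n = static_cast<int>(x.size());
  // order by y for equipartition
  std::vector<int> oy(n);
  for (int i = 0; i < n; ++i) oy[i] = i;
  std::sort(oy.begin(), oy.end(),
            [&](int a, int b) { return y[a] < y[b]; });
  std::vector<double> ysort(n);
  for (int i = 0; i < n; ++i) ysort[i] = y[oy[i]];
  // order by x (then y) for clumps
  std::vector<int> ox(n);
  for (int i = 0; i < n; ++i) ox[i] = i;
  std::sort(ox.begin(), ox.end(), [&](int a, int b) {
    if (x[a] != x[b]) return x[a] < x[b];
    return y[a] < y[b];
  });

  double best = 0.0;
  const int qmax = static_cast<int>(B / 2.0);
  std::vector<int> rowlab(n), rowx(n), ends, sends;
  std::vector<double> score;
  for (int q = 2; q <= qmax; ++q) {
    const int lmax = static_cast<int>(B / q);
    if (lmax < 2) break;
    int qeff = equipartition(ysort, q, rowlab);
    if (qeff < 2) continue;
    // map row labels back to original indices, then into x order
    std::vector<int> rowof(n);
    for (int i = 0; i < n; ++i) rowof[oy[i]] = rowlab[i];
    std::vector<double> xs(n);
    for (int i = 0; i < n; ++i) {
      xs[i] = x[ox[i]];
      rowx[i] = rowof[ox[i]];
    }
    clump_endpoints(xs, rowx, ends);
    superclumps(ends, n, cfac * lmax, sends);
    double hq = 0.0;
    {
      std::vector<double> cnt(qeff, 0.0);
      for (int i = 0; i < n; ++i) cnt[rowlab[i]] += 1.0;
      for (int b = 0; b < qeff; ++b)
        if (cnt[b] > 0) hq -= (cnt[b] / n) * std::log(cnt[b] / n);
    }
    optimize_axis(sends, rowx, qeff, lmax, hq, n, score);
    for (int l = 2; l <= lmax; ++l) {
      double denom = std::log(std::min(l, qeff));
      if (denom <= 0.0) continue;
      double v = score[l - 2] / denom;
      if (v > best) best = v;
    }
  }
  return best;
}

}  // namespace

//' @noRd
// [[Rcpp::export(name = ".mic_cpp")]]
double mic_cpp(NumericVector x, NumericVector y,
               double alpha = 0.6, int clump_factor = 15) {
  const int n = x.size();
  if (n != y.size()) stop("x and y must have equal length");
  std::vector<double> xv(x.begin(), x.end()), yv(y.begin(), y.end());
  double B = std::floor(std::pow(static_cast<double>(n), alpha));
  if (B < 4.0) B = 4.0;
  double m1 = mic_one_orientation(xv, yv, B, clump_factor);
  double m2 = mic_one_orientation(yv, xv, B, clump_factor);
  double v = std::max(m1, m2);
  if (v < 0.0) v = 0.0;
  if (v > 1.0) v = 1.0;
  return v;
}
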