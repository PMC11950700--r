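#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Deep dropout network: 2 hidden ReLU layers of equal width with inverted
// dropout after each, 1 sigmoid output unit, binary cross-entropy loss,
// Adam updates on shuffled mini-batches. All randomness (initialization,
// shuffling, dropout masks) comes from R's RNG stream, so set.seed() on
// the R side makes training fully reproducible.

namespace {

struct Net {
  int d, h;
  std::vector<double> W1, b1, W2, b2, W3;  // W1: d*h, W2: h*h, W3: h
  double b3;
};

inline double sigmoid(double z) { return 1.0 / (1.0 + std::exp(-z)); }

void glorot(std::vector<double> &w, int fan_in, int fan_out) {
  double lim = std::sqrt(6.0 / (fan_in + fan_out));
  for (size_t i = 0; i < w.size(); ++i)
    w[i] = (2.0 * unif_rand() - 1.0) * lim;
}

struct Adam {
  std::vector<double> m, v;
  double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  explicit Adam(size_t n) : m(n, 0.0), v(n, 0.0) {}
  void step(double *w, const double *g, size_t n, double lr, int t) {
    double c1 = 1.0 - std::pow(b1, t), c2 = 1.0 - std::pow(b2, t);
    for (size_t i = 0; i < n; ++i) {
      m[i] = b1 * m[i] + (1.0 - b1) * g[i];
      v[i] = b2 * v[i] + (1.0 - b2) * g[i] * g[i];
      w[i] -= lr * (m[i] / c1) / (std::sqrt(v[i] / c2) + eps);
    }
  }
};

}  // namespace

// [[Rcpp::export(name = ".ddn_train_cpp")]]
List ddn_train_cpp(NumericMatrix X, NumericVector y, int hidden,
                   double dropout, double lr, int epochs, int batch) {
  const int n = X.nrow(), d = X.ncol(), h = hidden;
  if (batch < 1) batch = 1;
  if (batch > n) batch = n;
  Net net;
  net.d = d; net.h = h;
  // small positive hidden biases keep ReLU units initially active,
  // avoiding dead networks at the very small widths this architecture
  // produces for short feature lists
  net.W1.resize(d * h); net.b1.assign(h, 0.1);
  net.W2.resize(h * h); net.b2.assign(h, 0.1);
  net.W3.resize(h);     net.b3 = 0.0;
  glorot(net.W1, d, h);
  glorot(net.W2, h, h);
  glorot(net.W3, h, 1);

  Adam aW1(d * h), ab1(h), aW2(h * h), ab2(h), aW3(h), ab3(1);
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;

  const double keep = 1.0 - dropout;
  std::vector<double> Xb(batch * d), yb(batch);
  std::vector<double> z1(batch * h), a1(batch * h), m1(batch * h);
  std::vector<double> z2(batch * h), a2(batch * h), m2(batch * h);
  std::vector<double> d3(batch), d2(batch * h), d1(batch * h);
  std::vector<double> gW1(d * h), gb1(h), gW2(h * h), gb2(h), gW3(h);
  int t = 0;

  for (int ep = 0; ep < epochs; ++ep) {
    // Fisher-Yates shuffle from R's RNG
    for (int i = n - 1; i > 0; --i) {
      int j = static_cast<int>(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(idx[i], idx[j]);
    }
    for (int off = 0; off < n; off += batch) {
      int m = std::min(batch, n - off);
      for (int r = 0; r < m; ++r) {
        int src = idx[off + r];
        for (int c = 0; c < d; ++c) Xb[r * d + c] = X(src, c);
        yb[r] = y[src];
      }
      // forward: layer 1
      for (int r = 0; r < m; ++r)
        for (int j = 0; j < h; ++j) {
          double z = net.b1[j];
          for (int c = 0; c < d; ++c) z += Xb[r * d + c] * net.W1[c * h + j];
          z1[r * h + j] = z;
          double a = z > 0.0 ? z : 0.0;
          double mask = 1.0;
          if (dropout > 0.0) mask = (unif_rand() < keep) ? 1.0 / keep : 0.0;
          m1[r * h + j] = mask;
          a1[r * h + j] = a * mask;
        }
      // layer 2
      for (int r = 0; r < m; ++r)
        for (int j = 0; j < h; ++j) {
          double z = net.b2[j];
          for (int c = 0; c < h; ++c) z += a1[r * h + c] * net.W2[c * h + j];
          z2[r * h + j] = z;
          double a = z > 0.0 ? z : 0.0;
          double mask = 1.0;
          if (dropout > 0.0) mask = (unif_rand() < keep) ? 1.0 / keep : 0.0;
          m2[r * h + j] = mask;
          a2[r * h + j] = a * mask;
        }
      // output + BCE gradient
      for (int r = 0; r < m; ++r) {
        double z = net.b3;
        for (int c = 0; c < h; ++c) z += a2[r * h + c] * net.W3[c];
        d3[r] = (sigmoid(z) - yb[r]) / m;
      }
      // backward
      std::fill(gW3.begin(), gW3.end(), 0.0);
      double gb3 = 0.0;
      for (int r = 0; r < m; ++r) {
        gb3 += d3[r];
        for (int c = 0; c < h; ++c) gW3[c] += a2[r * h + c] * d3[r];
      }
      for (int r = 0; r < m; ++r)
        for (int j = 0; j < h; ++j) {
          double v = d3[r] * net.W3[j];
          v *= m2[r * h + j];
          if (z2[r * h + j] <= 0.0) v = 0.0;
          d2[r * h + j] = v;
        }
      std::fill(gW2.begin(), gW2.end(), 0.0);
      std::fill(gb2.begin(), gb2.end(), 0.0);
      for (int r = 0; r < m; ++r)
        for (int j = 0; j < h; ++j) {
          double v = d2[r * h + j];
          if (v == 0.0) continue;
          gb2[j] += v;
          for (int c = 0; c < h; ++c) gW2[c * h + j] += a1[r * h + c] * v;
        }
      for (int r = 0; r < m; ++r)
        for (int j = 0; j < h; ++j) {
          double v = 0.0;
          for (int c = 0; c < h; ++c) v += d2[r * h + c] * net.W2[j * h + c];
          v *= m1[r * h + j];
          if (z1[r * h + j] <= 0.0) v = 0.0;
          d1[r * h + j] = v;
        }
      std::fill(gW1.begin(), gW1.end(), 0.0);
      std::fill(gb1.begin(), gb1.end(), 0.0);
      for (int r = 0; r < m; ++r)
        for (int j = 0; j < h; ++j) {
          double v = d1[r * h + j];
          if (v == 0.0) continue;
          gb1[j] += v;
          for (int c = 0; c < d; ++c) gW1[c * h + j] += Xb[r * d + c] * v;
        }
      ++t;
      aW1.step(net.W1.data(), gW1.data(), net.W1.size(), lr, t);
      ab1.step(net.b1.data(), gb1.data(), net.b1.size(), lr, t);
      aW2.step(net.W2.data(), gW2.data(), net.W2.size(), lr, t);
      ab2.step(net.b2.data(), gb2.data(), net.b2.size(), lr, t);
      aW3.step(net.W3.data(), gW3.data(), net.W3.size(), lr, t);
      double g3 = gb3;
      ab3.step(&net.b3, &g3, 1, lr, t);
    }
  }

  return List::create(
      Named("W1") = NumericVector(net.W1.begin(), net.W1.end()),
      Named("b1") = NumericVector(net.b1.begin(), net.b1.end()),
      Named("W2") = NumericVector(net.W2.begin(), net.W2.end()),
      Named("b2") = NumericVector(net.b2.begin(), net.b2.end()),
      Named("W3") = NumericVector(net.W3.begin(), net.W3.end()),
      Named("b3") = net.b3,
      Named("d") = d, Named("h") = h);
}

// [[Rcpp::export(name = ".ddn_predict_cpp")]]
NumericVector ddn_predict_cpp(List params, NumericMatrix X) {
  const int n = X.nrow();
  const int d = as<int>(params["d"]), h = as<int>(params["h"]);
  if (X.ncol() != d) stop("feature count mismatch");
  NumericVector W1 = params["W1"], b1 = params["b1"], W2 = params["W2"],
                b2 = params["b2"], W3 = params["W3"];
  double b3 = as<double>(params["b3"]);
  NumericVector out(n);
  std::vector<double> a1(h), a2(h);
  for (int r = 0; r < n; ++r) {
    for (int j = 0; j < h; ++j) {
      double z = b1[j];
      for (int c = 0; c < d; ++c) z += X(r, c) * W1[c * h + j];
      a1[j] = z > 0.0 ? z : 0.0;
    }
    for (int j = 0; j < h; ++j) {
      double z = b2[j];
      for (int c = 0; c < h; ++c) z += a1[c] * W2[c * h + j];
      a2[j] = z > 0.0 ? z : 0.0;
    }
    double z = b3;
    for (int c = 0; c < h; ++c) z += a2[c] * W3[c];
    out[r] = sigmoid(z);
  }
  return out;
}
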