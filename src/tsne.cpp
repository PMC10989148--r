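// Exact (O(N^2) gradient) t-SNE used for the 2D gene layout. The graphs the
// pipeline builds have a few thousand nodes at most, where the exact
// gradient is fast and removes the approximation error of tree-based
// variants; the Barnes-Hut accuracy parameter theta is accepted upstream for
// interface compatibility and documented as unused here.

#include <Rcpp.h>
#include <cfloat>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Squared Euclidean distance matrix of the rows of X.
static void squared_distances(const NumericMatrix& X,
                              std::vector<double>& d2) {
  const int n = X.nrow(), p = X.ncol();
  for (int i = 0; i < n; ++i) {
    d2[(size_t)i * n + i] = 0.0;
    for (int j = i + 1; j < n; ++j) {
      double s = 0.0;
      for (int k = 0; k < p; ++k) {
        const double diff = X(i, k) - X(j, k);
        s += diff * diff;
      }
      d2[(size_t)i * n + j] = s;
      d2[(size_t)j * n + i] = s;
    }
  }
}

// Binary search the Gaussian bandwidth of each point so the conditional
// distribution has the requested perplexity, then symmetrize.
static void input_similarities(const std::vector<double>& d2, int n,
                               double perplexity, std::vector<double>& P) {
  const double log_perp = std::log(perplexity);
  std::vector<double> row(n);
  for (int i = 0; i < n; ++i) {
    double beta = 1.0, beta_min = -INFINITY, beta_max = INFINITY;
    for (int iter = 0; iter < 60; ++iter) {
      double sum = 0.0, dsum = 0.0;
      for (int j = 0; j < n; ++j) {
        if (j == i) { row[j] = 0.0; continue; }
        const double v = std::exp(-beta * d2[(size_t)i * n + j]);
        row[j] = v;
        sum += v;
        dsum += d2[(size_t)i * n + j] * v;
      }
      if (sum <= 0) sum = DBL_MIN;
      // Shannon entropy of the conditional distribution.
      const double H = std::log(sum) + beta * dsum / sum;
      const double diff = H - log_perp;
      if (std::fabs(diff) < 1e-5) break;
      if (diff > 0) {  // entropy too high -> sharpen
        beta_min = beta;
        beta = std::isinf(beta_max) ? beta * 2.0 : (beta + beta_max) / 2.0;
      } else {
        beta_max = beta;
        beta = std::isinf(beta_min) ? beta / 2.0 : (beta + beta_min) / 2.0;
      }
    }
    double sum = 0.0;
    for (int j = 0; j < n; ++j) sum += row[j];
    if (sum <= 0) sum = DBL_MIN;
    for (int j = 0; j < n; ++j) P[(size_t)i * n + j] = row[j] / sum;
  }
  // Symmetrize and normalize to a joint distribution.
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      const double v = (P[(size_t)i * n + j] + P[(size_t)j * n + i]) /
                       (2.0 * n);
      P[(size_t)i * n + j] = std::max(v, 1e-12);
      P[(size_t)j * n + i] = P[(size_t)i * n + j];
    }
    P[(size_t)i * n + i] = 0.0;
  }
}

// [[Rcpp::export]]
NumericMatrix tsne_exact_cpp(NumericMatrix X, NumericMatrix Y0,
                             double perplexity, int max_iter,
                             double eta = 200.0, double exaggeration = 12.0,
                             int stop_lying_iter = 250,
                             int mom_switch_iter = 250) {
  const int n = X.nrow();
  std::vector<double> d2((size_t)n * n), P((size_t)n * n);
  squared_distances(X, d2);
  input_similarities(d2, n, perplexity, P);

  for (size_t k = 0; k < P.size(); ++k) P[k] *= exaggeration;

  NumericMatrix Y = clone(Y0);
  double* y = REAL(Y);  // column-major: x = y[i], y-coord = y[i + n]
  std::vector<double> dY((size_t)n * 2, 0.0), uY((size_t)n * 2, 0.0),
      gains((size_t)n * 2, 1.0);
  const size_t npairs = (size_t)n * (n - 1) / 2;
  std::vector<double> num(npairs), Ppair(npairs);
  {
    size_t id = 0;
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) Ppair[id++] = P[(size_t)i * n + j];
  }

  for (int iter = 0; iter < max_iter; ++iter) {
    // Pass 1: Student-t numerators and normalizer in the embedding.
    double Z = 0.0;
    {
      size_t id = 0;
      for (int i = 0; i < n; ++i) {
        const double yi0 = y[i], yi1 = y[i + n];
        for (int j = i + 1; j < n; ++j, ++id) {
          const double dx = yi0 - y[j], dy = yi1 - y[j + n];
          const double q = 1.0 / (1.0 + dx * dx + dy * dy);
          num[id] = q;
          Z += q;
        }
      }
    }
    Z *= 2.0;
    if (Z < DBL_MIN) Z = DBL_MIN;
    const double invZ = 1.0 / Z;

    // Pass 2: symmetric gradient accumulation over the upper triangle.
    std::fill(dY.begin(), dY.end(), 0.0);
    {
      size_t id = 0;
      for (int i = 0; i < n; ++i) {
        const double yi0 = y[i], yi1 = y[i + n];
        double gx = 0.0, gy = 0.0;
        for (int j = i + 1; j < n; ++j, ++id) {
          const double q = num[id];
          const double mult = (Ppair[id] - q * invZ) * q;
          const double dx = mult * (yi0 - y[j]);
          const double dy = mult * (yi1 - y[j + n]);
          gx += dx;
          gy += dy;
          dY[(size_t)j * 2] -= 4.0 * dx;
          dY[(size_t)j * 2 + 1] -= 4.0 * dy;
        }
        dY[(size_t)i * 2] += 4.0 * gx;
        dY[(size_t)i * 2 + 1] += 4.0 * gy;
      }
    }

    const double momentum = (iter < mom_switch_iter) ? 0.5 : 0.8;
    for (int i = 0; i < n; ++i) {
      for (int k = 0; k < 2; ++k) {
        const size_t id = (size_t)i * 2 + k;
        gains[id] = (std::signbit(dY[id]) != std::signbit(uY[id]))
                        ? gains[id] + 0.2
                        : gains[id] * 0.8;
        if (gains[id] < 0.01) gains[id] = 0.01;
        uY[id] = momentum * uY[id] - eta * gains[id] * dY[id];
        y[i + (size_t)k * n] += uY[id];
      }
    }
    // Re-center.
    double mx = 0.0, my = 0.0;
    for (int i = 0; i < n; ++i) { mx += y[i]; my += y[i + n]; }
    mx /= n; my /= n;
    for (int i = 0; i < n; ++i) { y[i] -= mx; y[i + n] -= my; }

    if (iter == stop_lying_iter - 1) {
      for (size_t k = 0; k < Ppair.size(); ++k) Ppair[k] /= exaggeration;
    }
  }
  return Y;
}
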