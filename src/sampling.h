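#pragma once
#include <vector>
#include <random>
#include <cstdint>
#include <cmath>
#include <stdexcept>

// Deterministic helpers on top of std::mt19937 (seeded per call from R).
// std::uniform_* distributions are implementation-defined, so uniforms are
// derived from raw 32-bit draws directly.
inline double rng01(std::mt19937 &g) {
  return (static_cast<double>(g()) + 0.5) / 4294967296.0;
}

inline int rng_below(std::mt19937 &g, int n) {
  int k = static_cast<int>(rng01(g) * n);
  return k >= n ? n - 1 : k;
}

inline double sigmoid_clip(double x) {
  if (x > 30.0) x = 30.0;
  if (x < -30.0) x = -30.0;
  return 1.0 / (1.0 + std::exp(-x));
}

// Walker alias table for O(1) draws from a discrete distribution.
struct AliasTable {
  std::vector<double> prob;
  std::vector<int> alias;

  void build(const std::vector<double> &w) {
    const int n = static_cast<int>(w.size());
    if (n == 0) throw std::runtime_error("alias table on empty weights");
    double total = 0.0;
    for (double x : w) {
      if (x < 0.0 || !std::isfinite(x)) throw std::runtime_error("invalid alias weight");
      total += x;
    }
    if (total <= 0.0) throw std::runtime_error("alias weights sum to zero");
    prob.assign(n, 0.0);
    alias.assign(n, 0);
    std::vector<double> scaled(n);
    std::vector<int> small, large;
    for (int i = 0; i < n; ++i) {
      scaled[i] = w[i] * n / total;
      (scaled[i] < 1.0 ? small : large).push_back(i);
    }
    while (!small.empty() && !large.empty()) {
      int s = small.back(); small.pop_back();
      int l = large.back(); large.pop_back();
      prob[s] = scaled[s];
      alias[s] = l;
      scaled[l] = scaled[l] + scaled[s] - 1.0;
      (scaled[l] < 1.0 ? small : large).push_back(l);
    }
    for (int i : small) prob[i] = 1.0;
    for (int i : large) prob[i] = 1.0;
  }

  int draw(std::mt19937 &g) const {
    int k = rng_below(g, static_cast<int>(prob.size()));
    return rng01(g) < prob[k] ? k : alias[k];
  }
};
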