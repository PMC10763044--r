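// LINE trainer: weighted edge sampling (alias method) + skip-gram style
// negative sampling from the degree^{3/4} noise distribution. Only the
// sampled optimizer lives here; the exact full-softmax objectives are
// computed in R.
#include <RcppArmadillo.h>
#include "sampling.h"
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// src/dst: 0-based endpoints of undirected edges; internally each edge is
// walked in both directions (standard LINE convention).
// [[Rcpp::export]]
List cpp_line_train(IntegerVector src, IntegerVector dst, NumericVector w,
                    int n, int dim, int order, int epochs, int negatives,
                    double lr0, int seed) {
  const int ne = src.size();
  if (ne == 0) stop("graph has no edges");
  std::mt19937 gen(static_cast<uint32_t>(seed));

  arma::mat emb(dim, n), ctx;
  for (arma::uword c = 0; c < emb.n_cols; ++c)
    for (arma::uword r = 0; r < emb.n_rows; ++r)
      emb(r, c) = (rng01(gen) - 0.5) / dim;
  if (order == 2) ctx.zeros(dim, n);

  // directed edge list and weighted degrees
  std::vector<int> di(2 * ne), dj(2 * ne);
  std::vector<double> dw(2 * ne), deg(n, 0.0);
  for (int e = 0; e < ne; ++e) {
    di[e] = src[e]; dj[e] = dst[e]; dw[e] = w[e];
    di[ne + e] = dst[e]; dj[ne + e] = src[e]; dw[ne + e] = w[e];
    deg[src[e]] += w[e];
    deg[dst[e]] += w[e];
  }
  AliasTable edge_alias; edge_alias.build(dw);
  std::vector<double> noise(n);
  for (int v = 0; v < n; ++v) noise[v] = std::pow(deg[v], 0.75);
  AliasTable noise_alias; noise_alias.build(noise);

  const long long total = static_cast<long long>(epochs) * 2LL * ne;
  arma::mat &target = (order == 2) ? ctx : emb;
  arma::vec err(dim);

  for (long long t = 0; t < total; ++t) {
    double lr = lr0 * std::max(1e-4, 1.0 - static_cast<double>(t) / total);
    int e = edge_alias.draw(gen);
    int i = di[e], j = dj[e];
    err.zeros();
    for (int k = 0; k <= negatives; ++k) {
      int tgt; double label;
      if (k == 0) { tgt = j; label = 1.0; }
      else {
        tgt = noise_alias.draw(gen);
        for (int tries = 0; (tgt == i || tgt == j) && tries < 100; ++tries)
          tgt = noise_alias.draw(gen);
        if (tgt == i || tgt == j) continue;
        label = 0.0;
      }
      double score = arma::dot(emb.col(i), target.col(tgt));
      double g = (label - sigmoid_clip(score)) * lr;
      err += g * target.col(tgt);
      target.col(tgt) += g * emb.col(i);
    }
    emb.col(i) += err;
  }
  if (!emb.is_finite()) stop("non-finite LINE gradient/update encountered");

  List out = List::create(_["emb"] = wrap(emb.t()));
  if (order == 2) out["ctx"] = wrap(ctx.t());
  return out;
}

// Loss and analytic gradients of one negative-sampling update:
//   L = -log sigma(u_c . u_pos) - sum_l log sigma(-u_c . u_neg_l)
// u_neg: dim x L. Used to cross-check the trainer's gradient arithmetic
// against central differences.
// [[Rcpp::export]]
List cpp_line_pair_grad(arma::vec u_c, arma::vec u_pos, arma::mat u_neg) {
  double s_pos = arma::dot(u_c, u_pos);
  double p = sigmoid_clip(s_pos);
  double loss = -std::log(p);
  arma::vec g_c = (p - 1.0) * u_pos;
  arma::vec g_pos = (p - 1.0) * u_c;
  arma::mat g_neg(u_neg.n_rows, u_neg.n_cols, arma::fill::zeros);
  for (arma::uword l = 0; l < u_neg.n_cols; ++l) {
    double s = arma::dot(u_c, u_neg.col(l));
    double q = sigmoid_clip(s);
    loss += -std::log(1.0 - q < 1e-300 ? 1e-300 : 1.0 - q);
    g_c += q * u_neg.col(l);
    g_neg.col(l) = q * u_c;
  }
  return List::create(_["loss"] = loss, _["g_center"] = g_c,
                      _["g_pos"] = g_pos, _["g_neg"] = g_neg);
}

// Empirical draw counts from an alias table, for distribution checks.
// [[Rcpp::export]]
IntegerVector cpp_alias_draw_counts(NumericVector w, int n_draws, int seed) {
  std::vector<double> wv(w.begin(), w.end());
  AliasTable a; a.build(wv);
  std::mt19937 gen(static_cast<uint32_t>(seed));
  IntegerVector counts(w.size());
  for (int t = 0; t < n_draws; ++t) counts[a.draw(gen)]++;
  return counts;
}
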