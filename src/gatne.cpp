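// Inductive GATNE core: mini-batch skip-gram training with negative
// sampling over meta-path walk pairs. Node embeddings are
//   v_{i,r} = H_z x_i + alpha_r M_r^T U_i c_{i,r} + beta_r D_z^T x_i
// with U_i the K-hop mean-aggregated edge embeddings of all relations and
// c_{i,r} the self-attention coefficients. K-hop aggregation with linear
// g_{z,r} collapses onto precomputed aggregated attribute matrices
// Xagg[t][z] (computed in R), because mean-aggregation commutes with the
// linear transforms.
#include <RcppArmadillo.h>
#include "sampling.h"
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

struct GModel {
  int ntype, m, d, s, a;
  std::vector<arma::mat> H;                    // per type: d x p_z
  std::vector<std::vector<arma::mat>> G;       // [rel][type]: s x p_z
  std::vector<arma::vec> wr;                   // per rel: a
  std::vector<arma::mat> Wr;                   // per rel: a x s
  std::vector<arma::mat> M;                    // per rel: s x d
  std::vector<arma::mat> D;                    // per type: p_z x d
  arma::vec alpha, beta;
  arma::mat ctx;                               // d x n
};

static GModel model_from_list(List ml) {
  GModel g;
  List H = ml["H"], G = ml["G"], wr = ml["w"], Wr = ml["W"], M = ml["M"], D = ml["D"];
  g.ntype = H.size();
  g.m = G.size();
  for (int z = 0; z < g.ntype; ++z) {
    g.H.push_back(as<arma::mat>(H[z]));
    g.D.push_back(as<arma::mat>(D[z]));
  }
  for (int r = 0; r < g.m; ++r) {
    List Gr = G[r];
    std::vector<arma::mat> row;
    for (int z = 0; z < g.ntype; ++z) row.push_back(as<arma::mat>(Gr[z]));
    g.G.push_back(row);
    g.wr.push_back(as<arma::vec>(wr[r]));
    g.Wr.push_back(as<arma::mat>(Wr[r]));
    g.M.push_back(as<arma::mat>(M[r]));
  }
  g.alpha = as<arma::vec>(ml["alpha"]);
  g.beta = as<arma::vec>(ml["beta"]);
  g.ctx = as<arma::mat>(ml["ctx"]);
  g.d = g.H[0].n_rows;
  g.s = g.G[0][0].n_rows;
  g.a = g.wr[0].n_elem;
  return g;
}

static List model_to_list(const GModel &g) {
  List H(g.ntype), D(g.ntype), G(g.m), wr(g.m), Wr(g.m), M(g.m);
  for (int z = 0; z < g.ntype; ++z) { H[z] = wrap(g.H[z]); D[z] = wrap(g.D[z]); }
  for (int r = 0; r < g.m; ++r) {
    List Gr(g.ntype);
    for (int z = 0; z < g.ntype; ++z) Gr[z] = wrap(g.G[r][z]);
    G[r] = Gr; wr[r] = wrap(g.wr[r]); Wr[r] = wrap(g.Wr[r]); M[r] = wrap(g.M[r]);
  }
  return List::create(_["H"] = H, _["G"] = G, _["w"] = wr, _["W"] = Wr,
                      _["M"] = M, _["D"] = D, _["alpha"] = wrap(g.alpha),
                      _["beta"] = wrap(g.beta), _["ctx"] = wrap(g.ctx));
}

struct GData {
  std::vector<arma::mat> X;                        // per type: p_z x n
  std::vector<std::vector<arma::mat>> Xagg;        // [rel][type]: p_z x n
};

static GData data_from_lists(List X, List Xagg, int m) {
  GData dat;
  for (int z = 0; z < X.size(); ++z) dat.X.push_back(as<arma::mat>(X[z]));
  for (int r = 0; r < m; ++r) {
    List Xr = Xagg[r];
    std::vector<arma::mat> row;
    for (int z = 0; z < Xr.size(); ++z) row.push_back(as<arma::mat>(Xr[z]));
    dat.Xagg.push_back(row);
  }
  return dat;
}

// Saved forward intermediates for one homogeneous group (shared center
// type z, shared relation r).
struct FwdCache {
  arma::mat XI;                 // p_z x B
  std::vector<arma::mat> Ut;    // per rel: s x B
  std::vector<arma::mat> At;    // per rel: a x B (tanh activations; m > 1)
  arma::mat C;                  // m x B attention coefficients
  arma::mat Uc;                 // s x B
  arma::mat V;                  // d x B
};

static void forward_group(const GModel &g, const GData &dat, int z, int r,
                          const arma::uvec &idx, FwdCache &fc) {
  const int B = idx.n_elem;
  fc.XI = dat.X[z].cols(idx);
  fc.Ut.assign(g.m, arma::mat());
  for (int t = 0; t < g.m; ++t) {
    arma::mat U(g.s, B, arma::fill::zeros);
    for (int z2 = 0; z2 < g.ntype; ++z2)
      U += g.G[t][z2] * dat.Xagg[t][z2].cols(idx);
    fc.Ut[t] = U;
  }
  if (g.m == 1) {
    fc.C.ones(1, B);
    fc.Uc = fc.Ut[0];
  } else {
    fc.At.assign(g.m, arma::mat());
    arma::mat Y(g.m, B);
    for (int t = 0; t < g.m; ++t) {
      fc.At[t] = arma::tanh(g.Wr[r] * fc.Ut[t]);
      Y.row(t) = g.wr[r].t() * fc.At[t];
    }
    Y.each_row() -= arma::max(Y, 0);
    fc.C = arma::exp(Y);
    fc.C.each_row() /= arma::sum(fc.C, 0);
    fc.Uc.zeros(g.s, B);
    for (int t = 0; t < g.m; ++t)
      fc.Uc += fc.Ut[t].each_row() % fc.C.row(t);
  }
  fc.V = g.H[z] * fc.XI + g.alpha[r] * (g.M[r].t() * fc.Uc)
       + g.beta[r] * (g.D[z].t() * fc.XI);
}

struct Grads {
  std::vector<arma::mat> H, D, M, Wr;
  std::vector<arma::vec> wr;
  std::vector<std::vector<arma::mat>> G;
  arma::mat ctx;

  void init(const GModel &g) {
    H.clear(); D.clear(); M.clear(); Wr.clear(); wr.clear(); G.clear();
    for (int z = 0; z < g.ntype; ++z) {
      H.push_back(arma::zeros(arma::size(g.H[z])));
      D.push_back(arma::zeros(arma::size(g.D[z])));
    }
    for (int r = 0; r < g.m; ++r) {
      M.push_back(arma::zeros(arma::size(g.M[r])));
      Wr.push_back(arma::zeros(arma::size(g.Wr[r])));
      wr.push_back(arma::zeros(arma::size(g.wr[r])));
      std::vector<arma::mat> row;
      for (int z = 0; z < g.ntype; ++z) row.push_back(arma::zeros(arma::size(g.G[r][z])));
      G.push_back(row);
    }
    ctx.zeros(arma::size(g.ctx));
  }
};

// Backpropagate Gv (d x B, the loss gradient w.r.t. V of the group) into
// the parameter gradient accumulators.
static void backward_group(const GModel &g, const GData &dat, int z, int r,
                           const arma::uvec &idx, const FwdCache &fc,
                           const arma::mat &Gv, Grads &gr) {
  gr.H[z] += Gv * fc.XI.t();
  gr.D[z] += g.beta[r] * (fc.XI * Gv.t());
  gr.M[r] += g.alpha[r] * (fc.Uc * Gv.t());
  arma::mat gUc = g.alpha[r] * (g.M[r] * Gv);            // s x B
  std::vector<arma::mat> gUt(g.m);
  if (g.m == 1) {
    gUt[0] = gUc;
  } else {
    const int B = idx.n_elem;
    arma::mat dC(g.m, B);
    for (int t = 0; t < g.m; ++t)
      dC.row(t) = arma::sum(fc.Ut[t] % gUc, 0);
    arma::rowvec inner = arma::sum(fc.C % dC, 0);
    arma::mat dY = fc.C % (dC.each_row() - inner);
    for (int t = 0; t < g.m; ++t) {
      gUt[t] = gUc.each_row() % fc.C.row(t);
      arma::mat dAt = g.wr[r] * dY.row(t);               // a x B
      arma::mat dZ = dAt % (1.0 - fc.At[t] % fc.At[t]);
      gr.wr[r] += fc.At[t] * dY.row(t).t();
      gr.Wr[r] += dZ * fc.Ut[t].t();
      gUt[t] += g.Wr[r].t() * dZ;
    }
  }
  for (int t = 0; t < g.m; ++t)
    for (int z2 = 0; z2 < g.ntype; ++z2)
      gr.G[t][z2] += gUt[t] * dat.Xagg[t][z2].cols(idx).t();
}

// Skip-gram negative-sampling loss of a group; fills Gv and the context
// gradient accumulator. negs: L x B (0-based vertex ids).
static double group_loss(const GModel &g, const FwdCache &fc,
                         const arma::uvec &ctrs, const arma::uvec &ctxs,
                         const arma::imat &negs, arma::mat &Gv, Grads &gr) {
  const int B = ctrs.n_elem;
  const int L = negs.n_rows;
  double loss = 0.0;
  Gv.zeros(g.d, B);
  for (int b = 0; b < B; ++b) {
    int j = ctxs[b];
    double sp = arma::dot(g.ctx.col(j), fc.V.col(b));
    double p = sigmoid_clip(sp);
    loss += -std::log(p);
    Gv.col(b) += (p - 1.0) * g.ctx.col(j);
    gr.ctx.col(j) += (p - 1.0) * fc.V.col(b);
    for (int l = 0; l < L; ++l) {
      int k = negs(l, b);
      if (k < 0) continue;
      double sn = arma::dot(g.ctx.col(k), fc.V.col(b));
      double q = sigmoid_clip(sn);
      double om = 1.0 - q < 1e-300 ? 1e-300 : 1.0 - q;
      loss += -std::log(om);
      Gv.col(b) += q * g.ctx.col(k);
      gr.ctx.col(k) += q * fc.V.col(b);
    }
  }
  return loss;
}

// Node embeddings v_{i,r} for a set of vertices (mixed types allowed).
// [[Rcpp::export]]
arma::mat cpp_gatne_forward(List model, List X, List Xagg,
                            IntegerVector types, int r, IntegerVector idx) {
  GModel g = model_from_list(model);
  GData dat = data_from_lists(X, Xagg, g.m);
  arma::mat V(g.d, idx.size());
  for (int z = 0; z < g.ntype; ++z) {
    std::vector<arma::uword> pos, verts;
    for (int b = 0; b < idx.size(); ++b) {
      if (types[idx[b]] == z) { pos.push_back(b); verts.push_back(idx[b]); }
    }
    if (pos.empty()) continue;
    arma::uvec vv(verts), pp(pos);
    FwdCache fc;
    forward_group(g, dat, z, r, vv, fc);
    V.cols(pp) = fc.V;
  }
  return V;
}

// Mini-batch SGD over (center, context, relation) skip-gram pairs.
// noise_w: per-type weight vectors (length n) for the negative-sampling
// distribution; negatives are drawn from the center vertex's type.
// [[Rcpp::export]]
List cpp_gatne_train(List model, List X, List Xagg, IntegerVector types,
                     IntegerVector centers, IntegerVector contexts,
                     IntegerVector rels, List noise_w, int epochs, int batch,
                     int L, double lr, int seed) {
  GModel g = model_from_list(model);
  GData dat = data_from_lists(X, Xagg, g.m);
  const int npair = centers.size();
  std::mt19937 gen(static_cast<uint32_t>(seed));

  std::vector<AliasTable> noise(g.ntype);
  for (int z = 0; z < g.ntype; ++z) {
    NumericVector wz = noise_w[z];
    std::vector<double> wv(wz.begin(), wz.end());
    noise[z].build(wv);
  }

  std::vector<int> order(npair);
  for (int p = 0; p < npair; ++p) order[p] = p;
  Grads gr;
  arma::mat Gv;
  NumericVector epoch_loss(epochs);

  for (int ep = 0; ep < epochs; ++ep) {
    // Fisher-Yates shuffle
    for (int p = npair - 1; p > 0; --p) {
      int q = rng_below(gen, p + 1);
      std::swap(order[p], order[q]);
    }
    double tot_loss = 0.0;
    for (int start = 0; start < npair; start += batch) {
      int B = std::min(batch, npair - start);
      // negatives drawn in batch order for determinism
      arma::imat negs(L, B);
      for (int b = 0; b < B; ++b) {
        int p = order[start + b];
        int i = centers[p], j = contexts[p];
        for (int l = 0; l < L; ++l) {
          int k = noise[types[i]].draw(gen);
          for (int tries = 0; (k == i || k == j) && tries < 100; ++tries)
            k = noise[types[i]].draw(gen);
          negs(l, b) = (k == i || k == j) ? -1 : k;
        }
      }
      gr.init(g);
      for (int r = 0; r < g.m; ++r) {
        for (int z = 0; z < g.ntype; ++z) {
          std::vector<arma::uword> verts, ctxs, cols;
          for (int b = 0; b < B; ++b) {
            int p = order[start + b];
            if (rels[p] == r && types[centers[p]] == z) {
              verts.push_back(centers[p]);
              ctxs.push_back(contexts[p]);
              cols.push_back(b);
            }
          }
          if (verts.empty()) continue;
          arma::uvec vv(verts), cc(ctxs), bb(cols);
          arma::imat gnegs(L, verts.size());
          for (arma::uword b = 0; b < bb.n_elem; ++b) gnegs.col(b) = negs.col(bb[b]);
          FwdCache fc;
          forward_group(g, dat, z, r, vv, fc);
          tot_loss += group_loss(g, fc, vv, cc, gnegs, Gv, gr);
          backward_group(g, dat, z, r, vv, fc, Gv, gr);
        }
      }
      double step = lr / B;
      for (int z = 0; z < g.ntype; ++z) { g.H[z] -= step * gr.H[z]; g.D[z] -= step * gr.D[z]; }
      for (int r = 0; r < g.m; ++r) {
        g.M[r] -= step * gr.M[r];
        g.Wr[r] -= step * gr.Wr[r];
        g.wr[r] -= step * gr.wr[r];
        for (int z = 0; z < g.ntype; ++z) g.G[r][z] -= step * gr.G[r][z];
      }
      g.ctx -= step * gr.ctx;
    }
    if (!std::isfinite(tot_loss)) {
      stop("non-finite GATNE loss at epoch %d; aborting (lr too large?)", ep + 1);
    }
    epoch_loss[ep] = tot_loss / npair;
  }
  List out = model_to_list(g);
  out["epoch_loss"] = epoch_loss;
  return out;
}

// Loss and analytic gradients of one skip-gram sample (center i, relation
// r, positive context j, fixed negatives) w.r.t. every parameter group.
// Exposed for central-difference gradient verification.
// [[Rcpp::export]]
List cpp_gatne_pair_grad(List model, List X, List Xagg, IntegerVector types,
                         int i, int r, int j, IntegerVector negs) {
  GModel g = model_from_list(model);
  GData dat = data_from_lists(X, Xagg, g.m);
  Grads gr;
  gr.init(g);
  arma::uvec vv(1); vv[0] = i;
  arma::uvec cc(1); cc[0] = j;
  arma::imat nn(negs.size(), 1);
  for (int l = 0; l < negs.size(); ++l) nn(l, 0) = negs[l];
  FwdCache fc;
  int z = types[i];
  forward_group(g, dat, z, r, vv, fc);
  arma::mat Gv;
  double loss = group_loss(g, fc, vv, cc, nn, Gv, gr);
  backward_group(g, dat, z, r, vv, fc, Gv, gr);

  List gH(g.ntype), gD(g.ntype), gG(g.m), gwr(g.m), gWr(g.m), gM(g.m);
  for (int zz = 0; zz < g.ntype; ++zz) { gH[zz] = wrap(gr.H[zz]); gD[zz] = wrap(gr.D[zz]); }
  for (int rr = 0; rr < g.m; ++rr) {
    List Gr(g.ntype);
    for (int zz = 0; zz < g.ntype; ++zz) Gr[zz] = wrap(gr.G[rr][zz]);
    gG[rr] = Gr; gwr[rr] = wrap(gr.wr[rr]); gWr[rr] = wrap(gr.Wr[rr]); gM[rr] = wrap(gr.M[rr]);
  }
  return List::create(_["loss"] = loss, _["H"] = gH, _["G"] = gG, _["w"] = gwr,
                      _["W"] = gWr, _["M"] = gM, _["D"] = gD,
                      _["ctx"] = wrap(gr.ctx), _["v"] = wrap(fc.V.col(0)));
}
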