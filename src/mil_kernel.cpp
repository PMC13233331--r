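// Batched forward/backward for the set-transformer MIL aggregator.
// Mirrors the base-R reference implementation (mil_fb_batch_r) exactly:
// bags are stacked into one tall matrix with one aggregation-token row per
// bag; row-wise operations run on the stack and attention loops per bag.
// The test suite asserts numerical identity with the R path.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::rowvec;
using arma::uvec;

static const double LN_EPS = 1e-5;

struct LnCache {
  mat xhat;
  vec sd;
};

static mat ln_forward(const mat& X, const rowvec& g, const rowvec& b,
                      LnCache& cache) {
  vec mu = arma::mean(X, 1);
  mat xc = X.each_col() - mu;
  vec sd = arma::sqrt(arma::mean(arma::square(xc), 1) + LN_EPS);
  cache.xhat = xc.each_col() / sd;
  cache.sd = sd;
  mat out = cache.xhat.each_row() % g;
  out.each_row() += b;
  return out;
}

static mat ln_backward(const mat& dY, const LnCache& cache, const rowvec& g,
                       rowvec& dg, rowvec& db) {
  mat dxhat = dY.each_row() % g;
  vec m1 = arma::mean(dxhat, 1);
  vec m2 = arma::mean(dxhat % cache.xhat, 1);
  dg = arma::sum(dY % cache.xhat, 0);
  db = arma::sum(dY, 0);
  mat dx = dxhat;
  dx.each_col() -= m1;
  dx -= cache.xhat.each_col() % m2;
  dx.each_col() /= cache.sd;
  return dx;
}

static mat softmax_rows(mat S) {
  vec m = arma::max(S, 1);
  S.each_col() -= m;
  S = arma::exp(S);
  vec rs = arma::sum(S, 1);
  S.each_col() /= rs;
  return S;
}

// [[Rcpp::export(name = ".cpp_fb_batch")]]
List cpp_fb_batch(List params, List Xs, IntegerVector labels,
                  NumericVector hb_z, int n_layers, int n_heads,
                  double hb_w, bool grad, Nullable<List> drop_masks,
                  double keep_p) {
  const int B = Xs.size();
  std::vector<mat> X(B);
  int n_total_cells = 0;
  for (int b = 0; b < B; ++b) {
    X[b] = as<mat>(Xs[b]);
    n_total_cells += X[b].n_rows;
  }
  mat W_in = as<mat>(params["W_in"]);
  rowvec b_in = as<rowvec>(params["b_in"]);
  rowvec cls = as<rowvec>(params["cls"]);
  const int L = W_in.n_cols;
  const int dh = L / n_heads;
  const int Ntot = n_total_cells + B;

  std::vector<int> start(B), size(B);
  {
    int pos = 0;
    for (int b = 0; b < B; ++b) {
      start[b] = pos;
      size[b] = X[b].n_rows + 1;
      pos += size[b];
    }
  }
  uvec starts(B), cellrows(n_total_cells);
  {
    int ci = 0;
    for (int b = 0; b < B; ++b) {
      starts[b] = start[b];
      for (int r = 1; r < size[b]; ++r) cellrows[ci++] = start[b] + r;
    }
  }

  mat Xall(n_total_cells, W_in.n_rows);
  {
    int pos = 0;
    for (int b = 0; b < B; ++b) {
      Xall.rows(pos, pos + X[b].n_rows - 1) = X[b];
      pos += X[b].n_rows;
    }
  }

  mat T(Ntot, L);
  {
    mat proj = Xall * W_in;
    proj.each_row() += b_in;
    T.rows(cellrows) = proj;
    for (int b = 0; b < B; ++b) T.row(starts[b]) = cls;
  }

  const bool use_drop = drop_masks.isNotNull();
  List masks;
  if (use_drop) masks = drop_masks.get();

  // per-layer caches
  std::vector<LnCache> ln1c(n_layers), ln2c(n_layers);
  std::vector<mat> Tin(n_layers), Yc(n_layers), Qc(n_layers), Kc(n_layers),
      Vc(n_layers), Hc(n_layers), T1c(n_layers), Y2c(n_layers),
      A1c(n_layers), Rdc(n_layers);
  std::vector<std::vector<mat>> Pc(n_layers);

  char nm[32];
  for (int l = 0; l < n_layers; ++l) {
    const int l1 = l + 1;
    snprintf(nm, sizeof(nm), "ln1_g_%d", l1);
    rowvec g1 = as<rowvec>(params[nm]);
    snprintf(nm, sizeof(nm), "ln1_b_%d", l1);
    rowvec bb1 = as<rowvec>(params[nm]);
    snprintf(nm, sizeof(nm), "Wq_%d", l1); mat Wq = as<mat>(params[nm]);
    snprintf(nm, sizeof(nm), "Wk_%d", l1); mat Wk = as<mat>(params[nm]);
    snprintf(nm, sizeof(nm), "Wv_%d", l1); mat Wv = as<mat>(params[nm]);
    snprintf(nm, sizeof(nm), "Wo_%d", l1); mat Wo = as<mat>(params[nm]);
    snprintf(nm, sizeof(nm), "bo_%d", l1); rowvec bo = as<rowvec>(params[nm]);
    snprintf(nm, sizeof(nm), "ln2_g_%d", l1);
    rowvec g2 = as<rowvec>(params[nm]);
    snprintf(nm, sizeof(nm), "ln2_b_%d", l1);
    rowvec bb2 = as<rowvec>(params[nm]);
    snprintf(nm, sizeof(nm), "W1_%d", l1); mat W1 = as<mat>(params[nm]);
    snprintf(nm, sizeof(nm), "b1_%d", l1); rowvec bf1 = as<rowvec>(params[nm]);
    snprintf(nm, sizeof(nm), "W2_%d", l1); mat W2 = as<mat>(params[nm]);
    snprintf(nm, sizeof(nm), "b2_%d", l1); rowvec bf2 = as<rowvec>(params[nm]);

    if (grad) Tin[l] = T;
    mat Y = ln_forward(T, g1, bb1, ln1c[l]);
    mat Q = Y * Wq, K = Y * Wk, V = Y * Wv;
    mat H(Ntot, L);
    std::vector<mat> Pl(B * n_heads);
    const double sc = 1.0 / std::sqrt((double)dh);
    for (int b = 0; b < B; ++b) {
      const int r0 = start[b], r1 = start[b] + size[b] - 1;
      for (int j = 0; j < n_heads; ++j) {
        const int c0 = j * dh, c1 = (j + 1) * dh - 1;
        mat S = Q.submat(r0, c0, r1, c1) * K.submat(r0, c0, r1, c1).t() * sc;
        mat P = softmax_rows(S);
        Pl[b * n_heads + j] = P;
        H.submat(r0, c0, r1, c1) = P * V.submat(r0, c0, r1, c1);
      }
    }
    mat O = H * Wo;
    O.each_row() += bo;
    mat T1 = T + O;
    mat Y2 = ln_forward(T1, g2, bb2, ln2c[l]);
    mat A1 = Y2 * W1;
    A1.each_row() += bf1;
    mat R = arma::clamp(A1, 0.0, arma::datum::inf);
    mat Rd = R;
    if (use_drop) {
      mat mask = as<mat>(masks[l]);
      Rd = R % mask / keep_p;
    }
    mat F2 = Rd * W2;
    F2.each_row() += bf2;
    T = T1 + F2;
    if (grad) {
      Yc[l] = Y; Qc[l] = Q; Kc[l] = K; Vc[l] = V; Hc[l] = H;
      T1c[l] = T1; Y2c[l] = Y2; A1c[l] = A1; Rdc[l] = Rd;
      Pc[l] = Pl;
    }
  }

  rowvec lnf_g = as<rowvec>(params["lnf_g"]);
  rowvec lnf_b = as<rowvec>(params["lnf_b"]);
  mat Wm = as<mat>(params["Wm"]);
  rowvec bm = as<rowvec>(params["bm"]);
  mat Wc = as<mat>(params["Wc"]);
  rowvec bc = as<rowvec>(params["bc"]);
  mat Wh = as<mat>(params["Wh"]);
  mat Whc = as<mat>(params["Whc"]);
  double bh = as<double>(params["bh"]);

  mat Tcls = T.rows(starts);
  LnCache lnfc;
  mat Z = ln_forward(Tcls, lnf_g, lnf_b, lnfc);
  mat Mpre = Z * Wm;
  Mpre.each_row() += bm;
  mat M = arma::clamp(Mpre, 0.0, arma::datum::inf);
  mat Md = M;
  mat head_mask;
  if (use_drop) {
    head_mask = as<mat>(masks[n_layers]);
    Md = M % head_mask / keep_p;
  }
  mat logits = Md * Wc;
  logits.each_row() += bc;
  mat probs = softmax_rows(logits);
  vec hbz = Md * Wh + logits * Whc;
  hbz += bh;

  vec ce(B), reg(B);
  for (int b = 0; b < B; ++b) {
    double pt = probs(b, labels[b] - 1);
    ce[b] = -std::log(std::max(pt, 1e-12));
    double d = hbz[b] - hb_z[b];
    reg[b] = d * d;
  }
  vec losses = ce + hb_w * reg;

  List out = List::create(
      Named("losses") = losses, Named("ce") = ce, Named("reg") = reg,
      Named("probs") = probs, Named("hbz") = hbz);
  if (!grad) return out;

  // ---- backward ----
  List g;
  mat dlogits = probs;
  vec dhbz(B);
  for (int b = 0; b < B; ++b) {
    dlogits(b, labels[b] - 1) -= 1.0;
    dhbz[b] = 2.0 * hb_w * (hbz[b] - hb_z[b]);
  }
  g["Whc"] = mat(logits.t() * dhbz);
  dlogits += dhbz * Whc.t();
  g["Wc"] = mat(Md.t() * dlogits);
  g["bc"] = rowvec(arma::sum(dlogits, 0));
  g["Wh"] = mat(Md.t() * dhbz);
  g["bh"] = arma::accu(dhbz);
  mat dMd = dlogits * Wc.t() + dhbz * Wh.t();
  mat dM = use_drop ? mat(dMd % head_mask / keep_p) : dMd;
  mat dMpre = dM % (Mpre > 0);
  g["Wm"] = mat(Z.t() * dMpre);
  g["bm"] = rowvec(arma::sum(dMpre, 0));
  mat dZ = dMpre * Wm.t();
  rowvec dgf, dbf;
  mat dTcls = ln_backward(dZ, lnfc, lnf_g, dgf, dbf);
  g["lnf_g"] = dgf;
  g["lnf_b"] = dbf;
  mat dT(Ntot, L, arma::fill::zeros);
  dT.rows(starts) = dTcls;

  for (int l = n_layers - 1; l >= 0; --l) {
    const int l1 = l + 1;
    snprintf(nm, sizeof(nm), "ln1_g_%d", l1);
    rowvec g1 = as<rowvec>(params[nm]);
    snprintf(nm, sizeof(nm), "Wq_%d", l1); mat Wq = as<mat>(params[nm]);
    snprintf(nm, sizeof(nm), "Wk_%d", l1); mat Wk = as<mat>(params[nm]);
    snprintf(nm, sizeof(nm), "Wv_%d", l1); mat Wv = as<mat>(params[nm]);
    snprintf(nm, sizeof(nm), "Wo_%d", l1); mat Wo = as<mat>(params[nm]);
    snprintf(nm, sizeof(nm), "ln2_g_%d", l1);
    rowvec g2 = as<rowvec>(params[nm]);
    snprintf(nm, sizeof(nm), "W1_%d", l1); mat W1 = as<mat>(params[nm]);
    snprintf(nm, sizeof(nm), "W2_%d", l1); mat W2 = as<mat>(params[nm]);

    // FFN block
    mat dF2 = dT;
    snprintf(nm, sizeof(nm), "W2_%d", l1);
    g[nm] = mat(Rdc[l].t() * dF2);
    snprintf(nm, sizeof(nm), "b2_%d", l1);
    g[nm] = rowvec(arma::sum(dF2, 0));
    mat dRd = dF2 * W2.t();
    mat dR = dRd;
    if (use_drop) {
      mat mask = as<mat>(masks[l]);
      dR = dRd % mask / keep_p;
    }
    mat dA1 = dR % (A1c[l] > 0);
    snprintf(nm, sizeof(nm), "W1_%d", l1);
    g[nm] = mat(Y2c[l].t() * dA1);
    snprintf(nm, sizeof(nm), "b1_%d", l1);
    g[nm] = rowvec(arma::sum(dA1, 0));
    mat dY2 = dA1 * W1.t();
    rowvec dg2, db2;
    mat dx2 = ln_backward(dY2, ln2c[l], g2, dg2, db2);
    snprintf(nm, sizeof(nm), "ln2_g_%d", l1); g[nm] = dg2;
    snprintf(nm, sizeof(nm), "ln2_b_%d", l1); g[nm] = db2;
    mat dT1 = dT + dx2;

    // attention block
    mat dO = dT1;
    snprintf(nm, sizeof(nm), "Wo_%d", l1);
    g[nm] = mat(Hc[l].t() * dO);
    snprintf(nm, sizeof(nm), "bo_%d", l1);
    g[nm] = rowvec(arma::sum(dO, 0));
    mat dH = dO * Wo.t();
    mat dQ(Ntot, L, arma::fill::zeros), dK(Ntot, L, arma::fill::zeros),
        dV(Ntot, L, arma::fill::zeros);
    const double sc = 1.0 / std::sqrt((double)dh);
    for (int b = 0; b < B; ++b) {
      const int r0 = start[b], r1 = start[b] + size[b] - 1;
      for (int j = 0; j < n_heads; ++j) {
        const int c0 = j * dh, c1 = (j + 1) * dh - 1;
        const mat& P = Pc[l][b * n_heads + j];
        mat dHj = dH.submat(r0, c0, r1, c1);
        mat dP = dHj * Vc[l].submat(r0, c0, r1, c1).t();
        dV.submat(r0, c0, r1, c1) = P.t() * dHj;
        vec rs = arma::sum(dP % P, 1);
        mat dS = (P % (dP.each_col() - rs)) * sc;
        dQ.submat(r0, c0, r1, c1) = dS * Kc[l].submat(r0, c0, r1, c1);
        dK.submat(r0, c0, r1, c1) = dS.t() * Qc[l].submat(r0, c0, r1, c1);
      }
    }
    snprintf(nm, sizeof(nm), "Wq_%d", l1);
    g[nm] = mat(Yc[l].t() * dQ);
    snprintf(nm, sizeof(nm), "Wk_%d", l1);
    g[nm] = mat(Yc[l].t() * dK);
    snprintf(nm, sizeof(nm), "Wv_%d", l1);
    g[nm] = mat(Yc[l].t() * dV);
    mat dY = dQ * Wq.t() + dK * Wk.t() + dV * Wv.t();
    rowvec dg1, db1;
    mat dx1 = ln_backward(dY, ln1c[l], g1, dg1, db1);
    snprintf(nm, sizeof(nm), "ln1_g_%d", l1); g[nm] = dg1;
    snprintf(nm, sizeof(nm), "ln1_b_%d", l1); g[nm] = db1;
    dT = dT1 + dx1;
  }

  g["cls"] = rowvec(arma::sum(dT.rows(starts), 0));
  mat dPin = dT.rows(cellrows);
  g["W_in"] = mat(Xall.t() * dPin);
  g["b_in"] = rowvec(arma::sum(dPin, 0));
  out["grads"] = g;
  return out;
}
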