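// Reference small convolutional classifier: forward/backward passes shared by
// the 2D (chest-radiograph-like) and 3D (brain-volume-like) adapters.
//
// Layout conventions (must match the R side):
//  * a batch of grayscale images is a (npix x B) matrix, pixels in R's
//    column-major array order over the spatial dims;
//  * an activation map is a (npix x C) matrix;
//  * conv weights for a block are ((3^nd * Cin) x Cout), column index of the
//    im2col matrix = ch * ntaps + tap;
//  * weights list order: W1, b1, ..., Wk, bk, Whead, bhead.
//
// Each block: 3^nd "same" convolution (zero pad 1) -> ReLU -> 2x average
// pool; then global average pool -> linear head (softmax / sigmoid / linear).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

struct LayerGeom {
  std::vector<int> dims;          // spatial extents at block input
  int npix;
  arma::Mat<int> nbr;             // npix x ntaps, -1 = zero pad
  arma::Mat<int> pool;            // npix_out x 2^nd children
  int npix_out;
};

int prod_dims(const std::vector<int>& d) {
  int p = 1;
  for (size_t i = 0; i < d.size(); ++i) p *= d[i];
  return p;
}

// neighbour table for a 3^nd kernel with zero padding 1
arma::Mat<int> build_nbr(const std::vector<int>& d) {
  const int nd = (int)d.size();
  int ntaps = 1;
  for (int i = 0; i < nd; ++i) ntaps *= 3;
  const int npix = prod_dims(d);
  arma::Mat<int> nbr(npix, ntaps);
  std::vector<int> stride(nd);
  stride[0] = 1;
  for (int i = 1; i < nd; ++i) stride[i] = stride[i - 1] * d[i - 1];
  std::vector<int> mi(nd);
  for (int p = 0; p < npix; ++p) {
    int r = p;
    for (int i = 0; i < nd; ++i) { mi[i] = r % d[i]; r /= d[i]; }
    for (int t = 0; t < ntaps; ++t) {
      int rt = t, q = 0;
      bool ok = true;
      for (int i = 0; i < nd; ++i) {
        int off = (rt % 3) - 1;
        rt /= 3;
        int c = mi[i] + off;
        if (c < 0 || c >= d[i]) { ok = false; break; }
        q += c * stride[i];
      }
      nbr(p, t) = ok ? q : -1;
    }
  }
  return nbr;
}

// 2x average pooling gather table (all extents must be even)
arma::Mat<int> build_pool(const std::vector<int>& d) {
  const int nd = (int)d.size();
  const int nchild = 1 << nd;
  std::vector<int> dh(nd);
  for (int i = 0; i < nd; ++i) dh[i] = d[i] / 2;
  const int nout = prod_dims(dh);
  std::vector<int> stride(nd);
  stride[0] = 1;
  for (int i = 1; i < nd; ++i) stride[i] = stride[i - 1] * d[i - 1];
  arma::Mat<int> pool(nout, nchild);
  std::vector<int> mi(nd);
  for (int o = 0; o < nout; ++o) {
    int r = o;
    for (int i = 0; i < nd; ++i) { mi[i] = r % dh[i]; r /= dh[i]; }
    for (int c = 0; c < nchild; ++c) {
      int q = 0;
      for (int i = 0; i < nd; ++i) {
        int delta = (c >> i) & 1;
        q += (2 * mi[i] + delta) * stride[i];
      }
      pool(o, c) = q;
    }
  }
  return pool;
}

arma::mat im2col(const arma::mat& A, const arma::Mat<int>& nbr) {
  const int npix = A.n_rows, cin = A.n_cols, ntaps = nbr.n_cols;
  arma::mat M(npix, ntaps * cin, arma::fill::zeros);
  for (int ch = 0; ch < cin; ++ch) {
    const double* acol = A.colptr(ch);
    for (int t = 0; t < ntaps; ++t) {
      double* mcol = M.colptr(ch * ntaps + t);
      const int* q = nbr.colptr(t);
      for (int p = 0; p < npix; ++p) if (q[p] >= 0) mcol[p] = acol[q[p]];
    }
  }
  return M;
}

arma::mat col2im(const arma::mat& dM, const arma::Mat<int>& nbr, int cin) {
  const int npix = dM.n_rows, ntaps = nbr.n_cols;
  arma::mat dA(npix, cin, arma::fill::zeros);
  for (int ch = 0; ch < cin; ++ch) {
    double* acol = dA.colptr(ch);
    for (int t = 0; t < ntaps; ++t) {
      const double* mcol = dM.colptr(ch * ntaps + t);
      const int* q = nbr.colptr(t);
      for (int p = 0; p < npix; ++p) if (q[p] >= 0) acol[q[p]] += mcol[p];
    }
  }
  return dA;
}

arma::mat pool_fwd(const arma::mat& Rm, const arma::Mat<int>& pool) {
  const int nout = pool.n_rows, nchild = pool.n_cols, C = Rm.n_cols;
  arma::mat P(nout, C, arma::fill::zeros);
  for (int ch = 0; ch < C; ++ch) {
    const double* rc = Rm.colptr(ch);
    double* pc = P.colptr(ch);
    for (int o = 0; o < nout; ++o) {
      double s = 0;
      for (int c = 0; c < nchild; ++c) s += rc[pool(o, c)];
      pc[o] = s / nchild;
    }
  }
  return P;
}

arma::mat pool_bwd(const arma::mat& dP, const arma::Mat<int>& pool, int npix_in) {
  const int nout = pool.n_rows, nchild = pool.n_cols, C = dP.n_cols;
  arma::mat dR(npix_in, C, arma::fill::zeros);
  for (int ch = 0; ch < C; ++ch) {
    const double* dpc = dP.colptr(ch);
    double* drc = dR.colptr(ch);
    for (int o = 0; o < nout; ++o) {
      double g = dpc[o] / nchild;
      for (int c = 0; c < nchild; ++c) drc[pool(o, c)] += g;
    }
  }
  return dR;
}

} // namespace

// One combined forward (+ optional backward) pass over a batch.
//
// X: npix x B. Y (optional): B x K targets. sw: per-sample weights.
// d_scores_extra: B x K gradient of an extra penalty w.r.t. scores.
// d_logits_in:    B x K gradient injected directly at the logits.
// d_feat_extra:   B x F gradient injected at the penultimate features.
// head: "softmax", "sigmoid" or "linear".
// [[Rcpp::export]]
List cnn_pass_cpp(List weights, const arma::mat& X,
                  IntegerVector dims_, IntegerVector channels_,
                  std::string head,
                  Nullable<NumericMatrix> Y_ = R_NilValue,
                  Nullable<NumericVector> sw_ = R_NilValue,
                  Nullable<NumericMatrix> d_scores_extra_ = R_NilValue,
                  Nullable<NumericMatrix> d_logits_in_ = R_NilValue,
                  Nullable<NumericMatrix> d_feat_extra_ = R_NilValue,
                  bool want_grads = false, bool want_input_grad = false,
                  bool want_conv = false, bool want_conv_grad = false) {
  const int nd = dims_.size();
  const int nblocks = channels_.size();
  const int B = X.n_cols;

  std::vector<LayerGeom> geom(nblocks);
  std::vector<int> d(nd);
  for (int i = 0; i < nd; ++i) d[i] = dims_[i];
  for (int b = 0; b < nblocks; ++b) {
    geom[b].dims = d;
    geom[b].npix = prod_dims(d);
    geom[b].nbr = build_nbr(d);
    geom[b].pool = build_pool(d);
    geom[b].npix_out = geom[b].pool.n_rows;
    for (int i = 0; i < nd; ++i) d[i] /= 2;
  }

  std::vector<arma::mat> W(nblocks), bW(nblocks);
  for (int b = 0; b < nblocks; ++b) {
    W[b] = as<arma::mat>(weights[2 * b]);
    bW[b] = as<arma::mat>(weights[2 * b + 1]);  // 1 x Cout
  }
  arma::mat Wh = as<arma::mat>(weights[2 * nblocks]);
  arma::mat bh = as<arma::mat>(weights[2 * nblocks + 1]);  // 1 x K
  const int F = Wh.n_rows, K = Wh.n_cols;
  const int npix_last = geom[nblocks - 1].npix_out;
  const int Clast = channels_[nblocks - 1];
  const int npix0 = geom[0].npix;

  const bool has_Y = Y_.isNotNull();
  arma::mat Y;
  if (has_Y) Y = as<arma::mat>(Y_.get());
  arma::vec sw(B, arma::fill::ones);
  if (sw_.isNotNull()) sw = as<arma::vec>(sw_.get());
  const double swsum = arma::accu(sw);
  arma::mat dS_extra, dL_in, dF_extra;
  const bool has_dS = d_scores_extra_.isNotNull();
  const bool has_dL = d_logits_in_.isNotNull();
  const bool has_dF = d_feat_extra_.isNotNull();
  if (has_dS) dS_extra = as<arma::mat>(d_scores_extra_.get());
  if (has_dL) dL_in = as<arma::mat>(d_logits_in_.get());
  if (has_dF) dF_extra = as<arma::mat>(d_feat_extra_.get());

  const bool backward = want_grads || want_input_grad || want_conv_grad;

  arma::mat scores(B, K), logits(B, K), feats(B, F);
  arma::cube conv_act, conv_grad;
  // last block post-ReLU (pre-pool) activations:
  const int npix_conv = geom[nblocks - 1].npix;
  if (want_conv) conv_act.set_size(npix_conv, Clast, B);
  if (want_conv_grad) conv_grad.set_size(npix_conv, Clast, B);

  List gW(2 * nblocks + 2);
  std::vector<arma::mat> dW(nblocks), dbv(nblocks);
  arma::mat dWh, dbh;
  if (want_grads) {
    for (int b = 0; b < nblocks; ++b) {
      dW[b] = arma::mat(W[b].n_rows, W[b].n_cols, arma::fill::zeros);
      dbv[b] = arma::mat(1, W[b].n_cols, arma::fill::zeros);
    }
    dWh = arma::mat(F, K, arma::fill::zeros);
    dbh = arma::mat(1, K, arma::fill::zeros);
  }
  arma::mat dX;
  if (want_input_grad) dX = arma::mat(npix0, B, arma::fill::zeros);

  double loss = 0.0;
  const double eps = 1e-7;

  std::vector<arma::mat> Ms(nblocks), Zs(nblocks);

  for (int s = 0; s < B; ++s) {
    arma::mat A = X.col(s);
    for (int b = 0; b < nblocks; ++b) {
      arma::mat M = im2col(A, geom[b].nbr);
      arma::mat Z = M * W[b];
      Z.each_row() += bW[b];
      arma::mat Rm = arma::clamp(Z, 0.0, arma::datum::inf);
      if (b == nblocks - 1 && want_conv) conv_act.slice(s) = Rm;
      A = pool_fwd(Rm, geom[b].pool);
      if (backward) { Ms[b] = std::move(M); Zs[b] = std::move(Z); }
    }
    arma::rowvec f = arma::mean(A, 0);  // 1 x Clast == F
    arma::rowvec lg = f * Wh + bh;
    arma::rowvec sc(K);
    if (head == "softmax") {
      arma::rowvec e = arma::exp(lg - lg.max());
      sc = e / arma::accu(e);
    } else if (head == "sigmoid") {
      sc = 1.0 / (1.0 + arma::exp(-lg));
    } else {
      sc = lg;
    }
    feats.row(s) = f;
    logits.row(s) = lg;
    scores.row(s) = sc;

    arma::rowvec dlg(K, arma::fill::zeros);
    if (has_Y) {
      arma::rowvec y = Y.row(s);
      arma::rowvec p = arma::clamp(sc, eps, 1.0 - eps);
      if (head == "softmax") {
        loss += -sw(s) * arma::accu(y % arma::log(p)) / swsum;
        dlg += (sw(s) / swsum) * (sc - y);
      } else {  // sigmoid / linear treated as BCE on [0,1] scores
        loss += -sw(s) * arma::accu(y % arma::log(p) +
                                    (1.0 - y) % arma::log(1.0 - p)) / (swsum * K);
        dlg += (sw(s) / (swsum * K)) * (sc - y);
      }
    }
    if (has_dS) {
      arma::rowvec g = dS_extra.row(s);
      if (head == "softmax") {
        dlg += sc % (g - arma::dot(g, sc));
      } else if (head == "sigmoid") {
        dlg += g % sc % (1.0 - sc);
      } else {
        dlg += g;
      }
    }
    if (has_dL) dlg += dL_in.row(s);

    if (!backward) continue;

    arma::rowvec dfeat = dlg * Wh.t();
    if (has_dF) dfeat += dF_extra.row(s);
    if (want_grads) {
      dWh += f.t() * dlg;
      dbh += dlg;
    }
    arma::mat dA(npix_last, Clast);
    for (int ch = 0; ch < Clast; ++ch) dA.col(ch).fill(dfeat(ch) / npix_last);
    for (int b = nblocks - 1; b >= 0; --b) {
      arma::mat dR = pool_bwd(dA, geom[b].pool, geom[b].npix);
      arma::mat dZ = dR % arma::conv_to<arma::mat>::from(Zs[b] > 0);
      if (b == nblocks - 1 && want_conv_grad) conv_grad.slice(s) = dR;
      if (want_grads) {
        dW[b] += Ms[b].t() * dZ;
        dbv[b] += arma::sum(dZ, 0);
      }
      if (b > 0 || want_input_grad) {
        arma::mat dM = dZ * W[b].t();
        int cin = (b == 0) ? 1 : channels_[b - 1];
        dA = col2im(dM, geom[b].nbr, cin);
      }
    }
    if (want_input_grad) dX.col(s) = dA.col(0);
  }

  List out = List::create(
      _["scores"] = scores, _["logits"] = logits, _["features"] = feats,
      _["loss"] = has_Y ? loss : NA_REAL);
  if (want_grads) {
    for (int b = 0; b < nblocks; ++b) {
      gW[2 * b] = dW[b];
      gW[2 * b + 1] = dbv[b];
    }
    gW[2 * nblocks] = dWh;
    gW[2 * nblocks + 1] = dbh;
    out["grads"] = gW;
  }
  if (want_input_grad) out["d_input"] = dX;
  if (want_conv) out["conv_act"] = conv_act;
  if (want_conv_grad) out["conv_grad"] = conv_grad;
  return out;
}
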