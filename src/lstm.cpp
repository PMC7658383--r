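// Three-layer LSTM sequence regressor (many-to-one) with a dropout layer
// before the linear read-out, trained with an RMSE loss and RMSprop.
// Single precision throughout: the dominant cost is sgemm and training at
// float32 is the convention for this model class.
//
// All randomness (weight init, epoch shuffling, dropout masks) is drawn from
// R's RNG so that set.seed() on the R side gives bitwise-reproducible runs.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct LstmLayer {
  fmat Wx;    // D x 4H   (gate order: input, forget, cell, output)
  fmat Wh;    // H x 4H
  frowvec b;  // 4H
};

struct Dense {
  fvec w;   // H
  float b;
};

inline fmat sigmoid(const fmat& x) { return 1.0f / (1.0f + exp(-x)); }

// Fast tanh: Pade(7,6) rational approximation, accurate to ~1e-7 on the
// unsaturated range, clamped to +/-1 beyond it. Elementwise gate activations
// dominate the non-BLAS cost, so these must vectorize.
inline float tanh_fast(float x) {
  if (x < -4.97f) return -1.0f;
  if (x > 4.97f) return 1.0f;
  const float x2 = x * x;
  const float p = x * (135135.0f + x2 * (17325.0f + x2 * (378.0f + x2)));
  const float q = 135135.0f + x2 * (62370.0f + x2 * (3150.0f + x2 * 28.0f));
  return p / q;
}
inline float sig_fast(float x) { return 0.5f + 0.5f * tanh_fast(0.5f * x); }

// Glorot-uniform init via R's RNG.
fmat glorot(uword nin, uword nout, uword nrow, uword ncol) {
  const double lim = std::sqrt(6.0 / (double)(nin + nout));
  fmat out(nrow, ncol);
  for (uword j = 0; j < ncol; ++j)
    for (uword i = 0; i < nrow; ++i)
      out(i, j) = (float)(R::runif(-lim, lim));
  return out;
}

// Per-layer forward caches needed by BPTT.
struct LayerCache {
  fcube gates;  // B x 4H x T (post-activation)
  fcube c;      // B x H x T
  fcube tc;     // B x H x T (tanh of cell state)
  fcube h;      // B x H x T
};

// Forward pass of one LSTM layer over a full sequence.
// inp: B x D x T. Returns h sequence through cache (cache.h).
void layer_forward(const LstmLayer& L, const fcube& inp, LayerCache& cache) {
  const uword B = inp.n_rows, D = inp.n_cols, T = inp.n_slices;
  const uword H = L.Wh.n_rows;

  // Batched input projection: one big sgemm over all timesteps.
  fmat big(B * T, D);
  for (uword t = 0; t < T; ++t) big.rows(t * B, t * B + B - 1) = inp.slice(t);
  fmat bigZ = big * L.Wx;  // (B*T) x 4H

  cache.gates.set_size(B, 4 * H, T);
  cache.c.set_size(B, H, T);
  cache.tc.set_size(B, H, T);
  cache.h.set_size(B, H, T);

  fmat a(B, 4 * H);
  const uword BH = B * H;
  for (uword t = 0; t < T; ++t) {
    a = bigZ.rows(t * B, t * B + B - 1);
    if (t > 0) a += cache.h.slice(t - 1) * L.Wh;
    a.each_row() += L.b;

    // Fused gate kernel: one pass over the batch-by-H block.
    const float* ap = a.memptr();
    const float* cp = (t > 0) ? cache.c.slice(t - 1).memptr() : nullptr;
    float* gp = cache.gates.slice(t).memptr();
    float* cs = cache.c.slice(t).memptr();
    float* ts = cache.tc.slice(t).memptr();
    float* hs = cache.h.slice(t).memptr();
    for (uword k = 0; k < BH; ++k) {
      const float gi = sig_fast(ap[k]);
      const float gf = sig_fast(ap[BH + k]);
      const float gg = tanh_fast(ap[2 * BH + k]);
      const float go = sig_fast(ap[3 * BH + k]);
      const float c = gf * (cp ? cp[k] : 0.0f) + gi * gg;
      const float tc = tanh_fast(c);
      gp[k] = gi;
      gp[BH + k] = gf;
      gp[2 * BH + k] = gg;
      gp[3 * BH + k] = go;
      cs[k] = c;
      ts[k] = tc;
      hs[k] = go * tc;
    }
  }
}

struct LayerGrads {
  fmat dWx, dWh;
  frowvec db;
};

// BPTT through one layer. dh_seq holds dL/dh_t for every t (contributions
// from the layer above; for the top layer only the last slice is non-zero).
// Returns dL/d(input sequence) and fills grads.
fcube layer_backward(const LstmLayer& L, const fcube& inp,
                     const LayerCache& cache, const fcube& dh_seq,
                     LayerGrads& g) {
  const uword B = inp.n_rows, D = inp.n_cols, T = inp.n_slices;
  const uword H = L.Wh.n_rows;

  g.dWx.zeros(D, 4 * H);
  g.dWh.zeros(H, 4 * H);
  g.db.zeros(4 * H);

  fcube dinp(B, D, T);
  fmat bigDa(B * T, 4 * H);
  fmat dh_next(B, H, fill::zeros), dc_next(B, H, fill::zeros);

  const uword BH = B * H;
  fmat da(B, 4 * H);
  for (uword t = T; t-- > 0;) {
    // Fused elementwise backward kernel.
    const float* dhs = dh_seq.slice(t).memptr();
    const float* dhn = dh_next.memptr();
    const float* gp = cache.gates.slice(t).memptr();
    const float* ts = cache.tc.slice(t).memptr();
    const float* cp = (t > 0) ? cache.c.slice(t - 1).memptr() : nullptr;
    float* dap = da.memptr();
    float* dcn = dc_next.memptr();
    for (uword k = 0; k < BH; ++k) {
      const float gi = gp[k], gf = gp[BH + k], gg = gp[2 * BH + k],
                  go = gp[3 * BH + k];
      const float tc = ts[k];
      const float dh = dhs[k] + dhn[k];
      const float dc = dh * go * (1.0f - tc * tc) + dcn[k];
      dap[k] = dc * gg * gi * (1.0f - gi);
      dap[BH + k] = dc * (cp ? cp[k] : 0.0f) * gf * (1.0f - gf);
      dap[2 * BH + k] = dc * gi * (1.0f - gg * gg);
      dap[3 * BH + k] = dh * tc * go * (1.0f - go);
      dcn[k] = dc * gf;
    }

    if (t > 0) g.dWh += cache.h.slice(t - 1).t() * da;
    bigDa.rows(t * B, t * B + B - 1) = da;
    dh_next = da * L.Wh.t();
    dinp.slice(t) = da * L.Wx.t();
  }
  g.db = sum(bigDa, 0);

  // dWx in one big sgemm.
  fmat big(B * T, D);
  for (uword t = 0; t < T; ++t) big.rows(t * B, t * B + B - 1) = inp.slice(t);
  g.dWx = big.t() * bigDa;
  return dinp;
}

struct RmspropState {
  std::vector<fmat> cache;
  double lr, rho, eps;
  void init(const std::vector<const fmat*>& params, double lr_, double rho_,
            double eps_) {
    lr = lr_; rho = rho_; eps = eps_;
    cache.clear();
    for (auto p : params) cache.emplace_back(size(*p), fill::zeros);
  }
  void step(std::vector<fmat*> params, const std::vector<const fmat*>& grads) {
    for (size_t k = 0; k < params.size(); ++k) {
      cache[k] = (float)rho * cache[k] +
                 (float)(1.0 - rho) * (*grads[k] % *grads[k]);
      *params[k] -= (float)lr * (*grads[k] / (sqrt(cache[k]) + (float)eps));
    }
  }
};

fcube subset_cube(const fcube& x, const uvec& idx) {
  fcube out(idx.n_elem, x.n_cols, x.n_slices);
  for (uword t = 0; t < x.n_slices; ++t)
    out.slice(t) = x.slice(t).rows(idx);
  return out;
}

}  // namespace

// x: N x D x T (samples x channels x lookback frames), y: length N.
// hidden: layer widths (e.g. 64, 128, 64).
// [[Rcpp::export(name = ".lstm_train")]]
Rcpp::List lstm_train(const arma::cube& x, const arma::vec& y,
                      const arma::ivec& hidden, double dropout, int epochs,
                      int batch_size, double lr, double rho, double eps,
                      bool shuffle) {
  Rcpp::RNGScope rng;
  const uword N = x.n_rows, D = x.n_cols, T = x.n_slices;
  const uword nl = hidden.n_elem;

  fcube xf = conv_to<fcube>::from(x);
  fvec yf = conv_to<fvec>::from(y);

  std::vector<LstmLayer> layers(nl);
  uword din = D;
  for (uword l = 0; l < nl; ++l) {
    const uword H = (uword)hidden(l);
    layers[l].Wx = glorot(din, H, din, 4 * H);
    layers[l].Wh = glorot(H, H, H, 4 * H);
    layers[l].b.zeros(4 * H);
    layers[l].b.subvec(H, 2 * H - 1).fill(1.0f);  // forget-gate bias
    din = H;
  }
  const uword Hl = (uword)hidden(nl - 1);
  Dense dense;
  dense.w = conv_to<fvec>::from(glorot(Hl, 1, Hl, 1));
  dense.b = 0.0f;

  // RMSprop state over every parameter tensor (dense packed as matrices).
  fmat dense_w(dense.w), dense_b(1, 1, fill::zeros);
  std::vector<fmat*> params;
  for (auto& L : layers) { params.push_back(&L.Wx); params.push_back(&L.Wh); }
  std::vector<fmat> bmats(nl);
  for (uword l = 0; l < nl; ++l) { bmats[l] = layers[l].b; params.push_back(&bmats[l]); }
  params.push_back(&dense_w);
  params.push_back(&dense_b);
  RmspropState opt;
  {
    std::vector<const fmat*> cp(params.begin(), params.end());
    opt.init(cp, lr, rho, eps);
  }

  const uword nb = (N + batch_size - 1) / batch_size;
  std::vector<double> history;
  history.reserve(epochs);

  uvec order = regspace<uvec>(0, N - 1);
  for (int ep = 0; ep < epochs; ++ep) {
    if (shuffle) {  // Fisher-Yates on R's RNG
      for (uword i = N - 1; i > 0; --i) {
        uword j = (uword)(R::unif_rand() * (double)(i + 1));
        if (j > i) j = i;
        std::swap(order(i), order(j));
      }
    }
    double ep_loss = 0.0;
    for (uword bi = 0; bi < nb; ++bi) {
      const uword lo = bi * batch_size;
      const uword hi = std::min<uword>(lo + batch_size, N) - 1;
      const uvec idx = order.subvec(lo, hi);
      const uword B = idx.n_elem;

      fcube xb = subset_cube(xf, idx);
      fvec yb = yf.elem(idx);

      // ---- forward ----
      std::vector<LayerCache> caches(nl);
      const fcube* inp = &xb;
      std::vector<const fcube*> inputs(nl);
      for (uword l = 0; l < nl; ++l) {
        inputs[l] = inp;
        layer_forward(layers[l], *inp, caches[l]);
        inp = &caches[l].h;
      }
      fmat hlast = caches[nl - 1].h.slice(T - 1);  // B x Hl

      // Inverted dropout on the read-out features.
      fmat mask(B, Hl, fill::ones);
      if (dropout > 0.0) {
        const float scale = 1.0f / (1.0f - (float)dropout);
        for (uword j = 0; j < Hl; ++j)
          for (uword i = 0; i < B; ++i)
            mask(i, j) = (R::unif_rand() < dropout) ? 0.0f : scale;
      }
      fmat hdrop = hlast % mask;
      fvec pred = hdrop * dense.w + dense.b;

      fvec resid = pred - yb;
      const double mse = dot(resid, resid) / (double)B;
      const double loss = std::sqrt(mse);
      ep_loss += loss;
      if (!std::isfinite(loss))
        Rcpp::stop("training diverged (non-finite loss) at epoch %d", ep + 1);

      // ---- backward ----
      // d(RMSE)/d(pred_i) = resid_i / (B * RMSE); guard the zero-loss case.
      fvec dpred = (loss > 0) ? fvec(resid / (float)((double)B * loss))
                              : fvec(B, fill::zeros);
      fmat dw_dense = hdrop.t() * dpred;          // Hl x 1
      fmat db_dense(1, 1);
      db_dense(0, 0) = accu(dpred);
      fmat dhdrop = dpred * dense.w.t();          // B x Hl
      fmat dhlast = dhdrop % mask;

      std::vector<LayerGrads> grads(nl);
      fcube dh_seq(B, Hl, T, fill::zeros);
      dh_seq.slice(T - 1) = dhlast;
      for (uword l = nl; l-- > 0;) {
        fcube dinp = layer_backward(layers[l], *inputs[l], caches[l],
                                    dh_seq, grads[l]);
        if (l > 0) dh_seq = std::move(dinp);
      }

      std::vector<const fmat*> gptr;
      for (uword l = 0; l < nl; ++l) { gptr.push_back(&grads[l].dWx); gptr.push_back(&grads[l].dWh); }
      std::vector<fmat> gb(nl);
      for (uword l = 0; l < nl; ++l) { gb[l] = grads[l].db; gptr.push_back(&gb[l]); }
      gptr.push_back(&dw_dense);
      gptr.push_back(&db_dense);
      opt.step(params, gptr);

      // biases live in bmats / dense_w for the optimizer; copy back
      for (uword l = 0; l < nl; ++l) layers[l].b = bmats[l];
      dense.w = dense_w.col(0);
      dense.b = dense_b(0, 0);
    }
    history.push_back(ep_loss / (double)nb);
    Rcpp::checkUserInterrupt();
  }

  Rcpp::List wl(nl);
  for (uword l = 0; l < nl; ++l) {
    wl[l] = Rcpp::List::create(
        Rcpp::Named("Wx") = conv_to<mat>::from(layers[l].Wx),
        Rcpp::Named("Wh") = conv_to<mat>::from(layers[l].Wh),
        Rcpp::Named("b") = conv_to<rowvec>::from(layers[l].b));
  }
  return Rcpp::List::create(
      Rcpp::Named("layers") = wl,
      Rcpp::Named("dense_w") = conv_to<vec>::from(dense.w),
      Rcpp::Named("dense_b") = (double)dense.b,
      Rcpp::Named("history") = history);
}

// Forward-only pass; dropout disabled (inverted dropout needs no rescale).
// [[Rcpp::export(name = ".lstm_predict")]]
arma::vec lstm_predict(Rcpp::List weights, const arma::cube& x) {
  Rcpp::List wl = weights["layers"];
  const uword nl = wl.size();
  std::vector<LstmLayer> layers(nl);
  for (uword l = 0; l < nl; ++l) {
    Rcpp::List li = wl[l];
    layers[l].Wx = conv_to<fmat>::from(Rcpp::as<mat>(li["Wx"]));
    layers[l].Wh = conv_to<fmat>::from(Rcpp::as<mat>(li["Wh"]));
    layers[l].b = conv_to<frowvec>::from(Rcpp::as<rowvec>(li["b"]));
  }
  fvec dw = conv_to<fvec>::from(Rcpp::as<vec>(weights["dense_w"]));
  const float db = (float)Rcpp::as<double>(weights["dense_b"]);

  const uword N = x.n_rows, T = x.n_slices;
  fcube xf = conv_to<fcube>::from(x);
  vec out(N);

  const uword chunk = 512;
  for (uword lo = 0; lo < N; lo += chunk) {
    const uword hi = std::min(lo + chunk, N) - 1;
    const uvec idx = regspace<uvec>(lo, hi);
    fcube xb = subset_cube(xf, idx);
    const uword B = xb.n_rows;

    std::vector<fmat> h(nl), c(nl);
    for (uword l = 0; l < nl; ++l) {
      const uword H = layers[l].Wh.n_rows;
      h[l].zeros(B, H);
      c[l].zeros(B, H);
    }
    for (uword t = 0; t < T; ++t) {
      fmat inp = xb.slice(t);
      for (uword l = 0; l < nl; ++l) {
        const uword H = layers[l].Wh.n_rows;
        fmat a = inp * layers[l].Wx + h[l] * layers[l].Wh;
        a.each_row() += layers[l].b;
        fmat gi = sigmoid(a.cols(0, H - 1));
        fmat gf = sigmoid(a.cols(H, 2 * H - 1));
        fmat gg = tanh(a.cols(2 * H, 3 * H - 1));
        fmat go = sigmoid(a.cols(3 * H, 4 * H - 1));
        c[l] = gf % c[l] + gi % gg;
        h[l] = go % tanh(c[l]);
        inp = h[l];
      }
    }
    fvec pred = h[nl - 1] * dw + db;
    out.subvec(lo, hi) = conv_to<vec>::from(pred);
  }
  return out;
}
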