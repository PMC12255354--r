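// Batched LSTM autoencoder forward/backward pass.
//
// Layout: a batch of n scaled RF vectors is a T x n matrix (T = 160 time
// steps). Each LSTM layer carries W (4H x D), U (4H x H), b (4H) with gate
// row blocks [i | f | g | o]. The encoder's final hidden state is repeated
// across T steps as the decoder input; a single-unit sigmoid layer, shared
// across time, maps the last decoder layer to the reconstruction.
//
// The pass runs in single precision with fused gate kernels — the standard
// arithmetic for neural-network training — while the optimizer (R side)
// accumulates in double. A slow double-precision reference implementation
// lives in R/autoencoder.R and the test suite checks the two agree.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct LayerCache {
  fcube i, f, g, o, tc, cp, hp; // gate activations and prior states per step
  fcube hs;                     // hidden outputs per step
};

inline float sigmf(float z) { return 1.0f / (1.0f + std::exp(-z)); }

// X: D x n x T input cube. Fills the cache (hs lives in the cache).
void lstm_fwd(const fmat& W, const fmat& U, const fvec& b, const fcube& X,
              LayerCache& c) {
  const uword H = b.n_elem / 4, n = X.n_cols, T = X.n_slices;
  c.i.set_size(H, n, T); c.f.set_size(H, n, T); c.g.set_size(H, n, T);
  c.o.set_size(H, n, T); c.tc.set_size(H, n, T);
  c.cp.set_size(H, n, T); c.hp.set_size(H, n, T);
  c.hs.set_size(H, n, T);
  fmat h(H, n, fill::zeros), cs(H, n, fill::zeros);
  fmat z(4 * H, n);
  for (uword t = 0; t < T; ++t) {
    z = W * X.slice(t) + U * h;
    z.each_col() += b;
    c.cp.slice(t) = cs;
    c.hp.slice(t) = h;
    float* zi = z.memptr();
    float* pi = c.i.slice_memptr(t); float* pf = c.f.slice_memptr(t);
    float* pg = c.g.slice_memptr(t); float* po = c.o.slice_memptr(t);
    float* ptc = c.tc.slice_memptr(t);
    float* ph = c.hs.slice_memptr(t);
    float* pcs = cs.memptr();
    for (uword col = 0; col < n; ++col) {
      const float* zc = zi + col * 4 * H;
      for (uword r = 0; r < H; ++r) {
        const float iv = sigmf(zc[r]);
        const float fv = sigmf(zc[H + r]);
        const float gv = std::tanh(zc[2 * H + r]);
        const float ov = sigmf(zc[3 * H + r]);
        const uword k = col * H + r;
        const float cc = fv * pcs[k] + iv * gv;
        const float tc = std::tanh(cc);
        pi[k] = iv; pf[k] = fv; pg[k] = gv; po[k] = ov;
        ptc[k] = tc;
        pcs[k] = cc;
        ph[k] = ov * tc;
      }
    }
    h = c.hs.slice(t);
  }
}

struct LayerGrad {
  fmat dW, dU;
  fvec db;
  fcube dX;
};

// dhs: H x n x T gradient w.r.t. the hidden outputs (zeros except the final
// slice for a last-state-only layer).
void lstm_bwd(const fmat& W, const fmat& U, const fcube& X,
              const LayerCache& c, const fcube& dhs, LayerGrad& g) {
  const uword H = c.i.n_rows, n = X.n_cols, T = X.n_slices;
  g.dW.zeros(W.n_rows, W.n_cols);
  g.dU.zeros(U.n_rows, U.n_cols);
  g.db.zeros(4 * H);
  g.dX.set_size(X.n_rows, n, T);
  fmat dh_next(H, n, fill::zeros), dc_next(H, n, fill::zeros);
  fmat dz(4 * H, n);
  for (uword t = T; t-- > 0;) {
    const float* pdh = dhs.slice_memptr(t);
    const float* pi = c.i.slice_memptr(t); const float* pf = c.f.slice_memptr(t);
    const float* pg = c.g.slice_memptr(t); const float* po = c.o.slice_memptr(t);
    const float* ptc = c.tc.slice_memptr(t);
    const float* pcp = c.cp.slice_memptr(t);
    float* pdz = dz.memptr();
    float* pdhn = dh_next.memptr();
    float* pdcn = dc_next.memptr();
    for (uword col = 0; col < n; ++col) {
      float* dzc = pdz + col * 4 * H;
      for (uword r = 0; r < H; ++r) {
        const uword k = col * H + r;
        const float dh = pdh[k] + pdhn[k];
        const float tc = ptc[k];
        const float dc = pdcn[k] + dh * po[k] * (1.0f - tc * tc);
        dzc[r] = dc * pg[k] * pi[k] * (1.0f - pi[k]);
        dzc[H + r] = dc * pcp[k] * pf[k] * (1.0f - pf[k]);
        dzc[2 * H + r] = dc * pi[k] * (1.0f - pg[k] * pg[k]);
        dzc[3 * H + r] = dh * tc * po[k] * (1.0f - po[k]);
        pdcn[k] = dc * pf[k];
      }
    }
    g.dW += dz * X.slice(t).t();
    g.dU += dz * c.hp.slice(t).t();
    g.db += sum(dz, 1);
    g.dX.slice(t) = W.t() * dz;
    dh_next = U.t() * dz;
  }
}

} // namespace

// Forward (and optionally backward) pass over one batch.
// layers: list of 6 lists (W, U, b); wy, by: output layer; Xb: T x n scaled
// inputs. Returns the reconstruction Y (T x n) and, when want_grads, the
// MSE-loss gradients for every parameter.
// [[Rcpp::export(name = ".ae_pass_cpp")]]
Rcpp::List ae_pass_cpp(Rcpp::List layers, const arma::vec& wy, double by,
                       const arma::mat& Xb, bool want_grads) {
  const uword T = Xb.n_rows, n = Xb.n_cols;
  std::vector<fmat> W(6), U(6);
  std::vector<fvec> b(6);
  for (int l = 0; l < 6; ++l) {
    Rcpp::List lay = layers[l];
    W[l] = conv_to<fmat>::from(Rcpp::as<mat>(lay["W"]));
    U[l] = conv_to<fmat>::from(Rcpp::as<mat>(lay["U"]));
    b[l] = conv_to<fvec>::from(Rcpp::as<vec>(lay["b"]));
  }
  fvec wyf = conv_to<fvec>::from(wy);
  const float byf = float(by);
  fmat Xf = conv_to<fmat>::from(Xb);

  fcube X0(1, n, T);
  for (uword t = 0; t < T; ++t) X0.slice(t) = Xf.row(t);

  std::vector<LayerCache> c(6);
  lstm_fwd(W[0], U[0], b[0], X0, c[0]);
  lstm_fwd(W[1], U[1], b[1], c[0].hs, c[1]);
  lstm_fwd(W[2], U[2], b[2], c[1].hs, c[2]);

  fmat h_enc = c[2].hs.slice(T - 1);
  fcube Xdec(h_enc.n_rows, n, T);
  for (uword t = 0; t < T; ++t) Xdec.slice(t) = h_enc;

  lstm_fwd(W[3], U[3], b[3], Xdec, c[3]);
  lstm_fwd(W[4], U[4], b[4], c[3].hs, c[4]);
  lstm_fwd(W[5], U[5], b[5], c[4].hs, c[5]);

  fmat Y(T, n);
  for (uword t = 0; t < T; ++t) {
    frowvec a = wyf.t() * c[5].hs.slice(t);
    for (uword col = 0; col < n; ++col) Y(t, col) = sigmf(a(col) + byf);
  }

  if (!want_grads)
    return Rcpp::List::create(Rcpp::Named("Y") = conv_to<mat>::from(Y));

  // dense output layer backward
  fmat dY = 2.0f * (Y - Xf) / float(T * n);
  const uword H6 = c[5].hs.n_rows;
  fvec dwy(H6, fill::zeros);
  float dby = 0.0f;
  fcube dh6(H6, n, T);
  for (uword t = 0; t < T; ++t) {
    frowvec dzy = dY.row(t) % Y.row(t) % (1.0f - Y.row(t));
    dwy += c[5].hs.slice(t) * dzy.t();
    dby += accu(dzy);
    dh6.slice(t) = wyf * dzy;
  }

  std::vector<LayerGrad> g(6);
  lstm_bwd(W[5], U[5], c[4].hs, c[5], dh6, g[5]);
  lstm_bwd(W[4], U[4], c[3].hs, c[4], g[5].dX, g[4]);
  lstm_bwd(W[3], U[3], Xdec, c[3], g[4].dX, g[3]);

  fmat dh_enc = sum(g[3].dX, 2);
  fcube dh3(c[2].hs.n_rows, n, T, fill::zeros);
  dh3.slice(T - 1) = dh_enc;
  lstm_bwd(W[2], U[2], c[1].hs, c[2], dh3, g[2]);
  lstm_bwd(W[1], U[1], c[0].hs, c[1], g[2].dX, g[1]);
  lstm_bwd(W[0], U[0], X0, c[0], g[1].dX, g[0]);

  Rcpp::List glayers(6);
  for (int l = 0; l < 6; ++l)
    glayers[l] = Rcpp::List::create(
        Rcpp::Named("dW") = conv_to<mat>::from(g[l].dW),
        Rcpp::Named("dU") = conv_to<mat>::from(g[l].dU),
        Rcpp::Named("db") = conv_to<vec>::from(g[l].db));
  return Rcpp::List::create(Rcpp::Named("Y") = conv_to<mat>::from(Y),
                            Rcpp::Named("layers") = glayers,
                            Rcpp::Named("dwy") = conv_to<vec>::from(dwy),
                            Rcpp::Named("dby") = double(dby));
}
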