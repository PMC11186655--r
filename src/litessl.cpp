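// Hot loops of the pipeline: patch extraction, the transformer block
// (forward and backward), and the fused augmentation view chain. The
// surrounding orchestration, parameter handling and all exported
// single-sequence operations stay in R; gradients computed here are
// verified against finite differences in the test suite.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;
using Rcpp::List;
using Rcpp::Named;

static const double INV_SQRT2 = 0.7071067811865475244;
static const double INV_SQRT2PI = 0.3989422804014326779;

static void softmax_rows_inplace(mat& S) {
  vec m = max(S, 1);
  S.each_col() -= m;
  S = exp(S);
  vec s = sum(S, 1);
  S.each_col() /= s;
}

// Row-wise layer normalization; returns y, and fills xhat / inv_sd caches.
static mat layernorm_fwd(const mat& X, const rowvec& g, const rowvec& b,
                         mat& xhat, vec& inv_sd) {
  vec mu = mean(X, 1);
  mat xc = X.each_col() - mu;
  vec v = mean(xc % xc, 1);
  inv_sd = 1.0 / sqrt(v + 1e-6);
  xhat = xc.each_col() % inv_sd;
  mat y = xhat.each_row() % g;
  y.each_row() += b;
  return y;
}

static mat layernorm_bwd(const mat& dy, const mat& xhat, const vec& inv_sd,
                         const rowvec& g, rowvec& dg, rowvec& db) {
  mat dxhat = dy.each_row() % g;
  vec m1 = mean(dxhat, 1);
  vec m2 = mean(dxhat % xhat, 1);
  dg = sum(dy % xhat, 0);
  db = sum(dy, 0);
  mat dx = dxhat.each_col() - m1;
  dx -= xhat.each_col() % m2;
  dx.each_col() %= inv_sd;
  return dx;
}

// (H,W,C,B) pixel array -> (P*P*C) x (B*N_patch) matrix with one flattened
// patch per column (the transpose of the patch-sequence layout; callers
// use crossprod). Within a patch: channel fastest, then column, then row;
// patches row-major over the tile grid; batch slowest.
// [[Rcpp::export]]
arma::mat patchify_t_cpp(const Rcpp::NumericVector& images, int H, int W,
                         int C, int B, int P, double scale,
                         double offset) {
  const int nh = H / P, nw = W / P, N = nh * nw, plen = P * P * C;
  mat out(plen, (size_t)B * N);
  const double* px = images.begin();
  double* o = out.memptr();
  const size_t sW = H, sC = (size_t)H * W, sB = (size_t)H * W * C;
  for (int b = 0; b < B; ++b) {
    for (int gh = 0; gh < nh; ++gh) {
      for (int gw = 0; gw < nw; ++gw) {
        for (int pr = 0; pr < P; ++pr) {
          for (int pc = 0; pc < P; ++pc) {
            const size_t base = (size_t)(gh * P + pr) +
                                sW * (size_t)(gw * P + pc) + sB * (size_t)b;
            for (int ch = 0; ch < C; ++ch) {
              *o++ = px[base + sC * (size_t)ch] * scale + offset;
            }
          }
        }
      }
    }
  }
  return out;
}

// Cached activations of one transformer block, kept on the C++ side
// (external pointer) so the backward pass avoids copying them through R.
struct BlockCache {
  mat xhat1, H1, heads, xhat2, H2, F1, G;
  vec inv1, inv2;
  cube qkv, A;
};

// One pre-norm transformer block, batched over B token sequences of length
// T stored contiguously in X ((B*T) x D).
// [[Rcpp::export]]
List block_forward_cpp(const arma::mat& X, const arma::cube& Uqkv,
                       const arma::mat& Uout, const arma::rowvec& g1,
                       const arma::rowvec& be1, const arma::rowvec& g2,
                       const arma::rowvec& be2, const arma::mat& W1,
                       const arma::rowvec& b1, const arma::mat& W2,
                       const arma::rowvec& b2, int B, int T,
                       bool keep_cache) {
  const int k = Uqkv.n_slices;
  const int Dh = Uqkv.n_cols / 3;
  const double scale = 1.0 / std::sqrt((double)Dh);
  mat xhat1, xhat2;
  vec inv1, inv2;
  mat H1 = layernorm_fwd(X, g1, be1, xhat1, inv1);
  cube qkv(X.n_rows, 3 * Dh, k);
  for (int h = 0; h < k; ++h) qkv.slice(h) = H1 * Uqkv.slice(h);
  mat heads(X.n_rows, k * Dh);
  cube A(T, T, keep_cache ? (size_t)B * k : 1);
  for (int b = 0; b < B; ++b) {
    const int r0 = b * T, r1 = b * T + T - 1;
    for (int h = 0; h < k; ++h) {
      mat S = qkv.slice(h).submat(r0, 0, r1, Dh - 1) *
              qkv.slice(h).submat(r0, Dh, r1, 2 * Dh - 1).t() * scale;
      softmax_rows_inplace(S);
      heads.submat(r0, h * Dh, r1, (h + 1) * Dh - 1) =
          S * qkv.slice(h).submat(r0, 2 * Dh, r1, 3 * Dh - 1);
      if (keep_cache) A.slice((size_t)b * k + h) = S;
    }
  }
  mat X1 = heads * Uout + X;
  mat H2 = layernorm_fwd(X1, g2, be2, xhat2, inv2);
  mat F1 = H2 * W1;
  F1.each_row() += b1;
  mat G = 0.5 * (F1 % (1.0 + erf(F1 * INV_SQRT2)));
  mat X2 = G * W2 + X1;
  X2.each_row() += b2;
  if (!keep_cache) return List::create(Named("X") = X2);
  BlockCache* cc = new BlockCache();
  cc->xhat1 = std::move(xhat1); cc->inv1 = std::move(inv1);
  cc->H1 = std::move(H1); cc->qkv = std::move(qkv);
  cc->A = std::move(A); cc->heads = std::move(heads);
  cc->xhat2 = std::move(xhat2); cc->inv2 = std::move(inv2);
  cc->H2 = std::move(H2); cc->F1 = std::move(F1); cc->G = std::move(G);
  Rcpp::XPtr<BlockCache> ptr(cc, true);
  return List::create(Named("X") = X2, Named("cache") = ptr);
}

// [[Rcpp::export]]
List block_backward_cpp(const arma::mat& dX2, const arma::cube& Uqkv,
                        const arma::mat& Uout, const arma::rowvec& g1,
                        const arma::rowvec& g2, const arma::mat& W1,
                        const arma::mat& W2, SEXP cache, int B, int T) {
  Rcpp::XPtr<BlockCache> cc(cache);
  const mat& xhat1 = cc->xhat1; const vec& inv1 = cc->inv1;
  const mat& H1 = cc->H1; const cube& qkv = cc->qkv;
  const cube& A = cc->A; const mat& heads = cc->heads;
  const mat& xhat2 = cc->xhat2; const vec& inv2 = cc->inv2;
  const mat& H2 = cc->H2; const mat& F1 = cc->F1; const mat& G = cc->G;
  const int k = Uqkv.n_slices;
  const int Dh = Uqkv.n_cols / 3;
  const double scale = 1.0 / std::sqrt((double)Dh);
  // MLP branch
  mat dW2 = G.t() * dX2;
  rowvec db2 = sum(dX2, 0);
  mat dG = dX2 * W2.t();
  mat Phi = 0.5 * (1.0 + erf(F1 * INV_SQRT2));
  mat dF1 = dG % (Phi + F1 % exp(-0.5 * F1 % F1) * INV_SQRT2PI);
  mat dW1 = H2.t() * dF1;
  rowvec db1 = sum(dF1, 0);
  mat dH2 = dF1 * W1.t();
  rowvec dg2, dbe2;
  mat dX1 = dX2 + layernorm_bwd(dH2, xhat2, inv2, g2, dg2, dbe2);
  // attention branch
  mat dUout = heads.t() * dX1;
  mat dheads = dX1 * Uout.t();
  cube dUqkv(Uqkv.n_rows, 3 * Dh, k);
  mat dH1(dX2.n_rows, dX2.n_cols, fill::zeros);
  mat dqkv_h(dX2.n_rows, 3 * Dh);
  for (int h = 0; h < k; ++h) {
    for (int b = 0; b < B; ++b) {
      const int r0 = b * T, r1 = b * T + T - 1;
      const mat& Ab = A.slice((size_t)b * k + h);
      mat dO = dheads.submat(r0, h * Dh, r1, (h + 1) * Dh - 1);
      mat dA = dO * qkv.slice(h).submat(r0, 2 * Dh, r1, 3 * Dh - 1).t();
      vec rs = sum(dA % Ab, 1);
      mat dS = Ab % (dA.each_col() - rs);
      dqkv_h.submat(r0, 0, r1, Dh - 1) =
          dS * qkv.slice(h).submat(r0, Dh, r1, 2 * Dh - 1) * scale;
      dqkv_h.submat(r0, Dh, r1, 2 * Dh - 1) =
          dS.t() * qkv.slice(h).submat(r0, 0, r1, Dh - 1) * scale;
      dqkv_h.submat(r0, 2 * Dh, r1, 3 * Dh - 1) = Ab.t() * dO;
    }
    dUqkv.slice(h) = H1.t() * dqkv_h;
    dH1 += dqkv_h * Uqkv.slice(h).t();
  }
  rowvec dg1, dbe1;
  mat dX0 = dX1 + layernorm_bwd(dH1, xhat1, inv1, g1, dg1, dbe1);
  return List::create(
      Named("dX") = dX0, Named("dUqkv") = dUqkv, Named("dUout") = dUout,
      Named("dW1") = dW1, Named("db1") = db1, Named("dW2") = dW2,
      Named("db2") = db2, Named("dg1") = dg1, Named("dbe1") = dbe1,
      Named("dg2") = dg2, Named("dbe2") = dbe2);
}

static inline double reflect1(double x, int n) {
  if (n == 1) return 1.0;
  double period = 2.0 * (n - 1);
  double u = (x - 1.0) / period;
  double t = (u - std::floor(u)) * period;
  return n - std::abs(t - (n - 1));
}

// Affine resample src = center + (dest - center)/scale - shift, bilinear
// with reflection padding. img: H x W x C.
// [[Rcpp::export]]
arma::cube warp_bilinear_cpp(const arma::cube& img, double scale,
                             double dx, double dy) {
  const int H = img.n_rows, W = img.n_cols, C = img.n_slices;
  const double cr = (H + 1) / 2.0, cc = (W + 1) / 2.0;
  cube out(H, W, C);
  std::vector<int> r0(H), c0(W);
  std::vector<double> wr(H), wc(W);
  for (int r = 0; r < H; ++r) {
    double sr = reflect1(cr + (r + 1 - cr) / scale - dy, H);
    int f = (H > 1) ? std::min((int)std::floor(sr), H - 1) : 1;
    r0[r] = f - 1;
    wr[r] = sr - f;
  }
  for (int c = 0; c < W; ++c) {
    double sc = reflect1(cc + (c + 1 - cc) / scale - dx, W);
    int f = (W > 1) ? std::min((int)std::floor(sc), W - 1) : 1;
    c0[c] = f - 1;
    wc[c] = sc - f;
  }
  for (int ch = 0; ch < C; ++ch) {
    const mat& M = img.slice(ch);
    mat& O = out.slice(ch);
    for (int c = 0; c < W; ++c) {
      int cl = c0[c], cu = std::min(cl + 1, W - 1);
      double w = wc[c];
      for (int r = 0; r < H; ++r) {
        int rl = r0[r], ru = std::min(rl + 1, H - 1);
        double v = wr[r];
        O(r, c) = (1 - v) * ((1 - w) * M(rl, cl) + w * M(rl, cu)) +
                  v * ((1 - w) * M(ru, cl) + w * M(ru, cu));
      }
    }
  }
  return out;
}

// Fused augmentation chain for one view: per-image min-max rescale to
// [lo, hi] (optional), mirror flips, translation followed by zoom (one
// bilinear resample with reflection padding), per-channel color affine,
// clip. Pointwise maps commute with the gather, so the chain is applied
// per output pixel in one pass.
// [[Rcpp::export]]
arma::cube view_chain_cpp(const arma::cube& img, bool minmax, double lo,
                          double hi, bool flip_h, bool flip_v, double dx,
                          double dy, double zoom, const arma::vec& gains,
                          const arma::vec& offsets) {
  const int H = img.n_rows, W = img.n_cols, C = img.n_slices;
  double rmin = img.min(), rmax = img.max();
  double a = 0.0, b0 = lo;
  if (minmax) {
    if (rmax > rmin) {
      a = (hi - lo) / (rmax - rmin);
      b0 = lo - rmin * a;
    } // constant image: maps to lo
  } else {
    a = 1.0; b0 = 0.0;
  }
  const double cr = (H + 1) / 2.0, cc = (W + 1) / 2.0;
  cube out(H, W, C);
  std::vector<int> r0(H), c0(W);
  std::vector<double> wr(H), wc(W);
  for (int r = 0; r < H; ++r) {
    double sr = reflect1(cr + (r + 1 - cr) / zoom - dy, H);
    if (flip_v) sr = H + 1 - sr;
    int f = (H > 1) ? std::min((int)std::floor(sr), H - 1) : 1;
    r0[r] = f - 1;
    wr[r] = sr - f;
  }
  for (int c = 0; c < W; ++c) {
    double sc = reflect1(cc + (c + 1 - cc) / zoom - dx, W);
    if (flip_h) sc = W + 1 - sc;
    int f = (W > 1) ? std::min((int)std::floor(sc), W - 1) : 1;
    c0[c] = f - 1;
    wc[c] = sc - f;
  }
  for (int ch = 0; ch < C; ++ch) {
    const mat& M = img.slice(ch);
    mat& O = out.slice(ch);
    const double g = gains(ch), off = offsets(ch);
    for (int c = 0; c < W; ++c) {
      int cl = c0[c], cu = std::min(cl + 1, W - 1);
      double w = wc[c];
      for (int r = 0; r < H; ++r) {
        int rl = r0[r], ru = std::min(rl + 1, H - 1);
        double v = wr[r];
        double val = (1 - v) * ((1 - w) * M(rl, cl) + w * M(rl, cu)) +
                     v * ((1 - w) * M(ru, cl) + w * M(ru, cu));
        val = (a * val + b0) * g + off;
        if (val < lo) val = lo;
        if (val > hi) val = hi;
        O(r, c) = val;
      }
    }
  }
  return out;
}

// Batched version of the view chain for the pretraining loop: applies one
// parameter row per output view, reading source images in place.
// pars columns: flip_h, flip_v, dx, dy, zoom, gains[C], offsets[C].
// [[Rcpp::export]]
Rcpp::NumericVector augment_views_cpp(const Rcpp::NumericVector& images,
                                      int H, int W, int C,
                                      const arma::uvec& src,
                                      const arma::mat& pars, bool minmax,
                                      double lo, double hi) {
  const int V = src.n_elem;
  const size_t npix = (size_t)H * W * C;
  Rcpp::NumericVector out((R_xlen_t)npix * V);
  const double* px = images.begin();
  std::vector<int> r0(H), c0(W);
  std::vector<double> wr(H), wc(W);
  const double cr = (H + 1) / 2.0, cc = (W + 1) / 2.0;
  for (int v = 0; v < V; ++v) {
    const double* im = px + npix * src(v);
    double* o = out.begin() + npix * (size_t)v;
    const bool fh = pars(v, 0) > 0.5, fv = pars(v, 1) > 0.5;
    const double dx = pars(v, 2), dy = pars(v, 3), zoom = pars(v, 4);
    double rmin = im[0], rmax = im[0];
    if (minmax) {
      for (size_t i = 1; i < npix; ++i) {
        if (im[i] < rmin) rmin = im[i];
        if (im[i] > rmax) rmax = im[i];
      }
    }
    double a = 1.0, b0 = 0.0;
    if (minmax) {
      if (rmax > rmin) {
        a = (hi - lo) / (rmax - rmin);
        b0 = lo - rmin * a;
      } else { a = 0.0; b0 = lo; }
    }
    for (int r = 0; r < H; ++r) {
      double sr = reflect1(cr + (r + 1 - cr) / zoom - dy, H);
      if (fv) sr = H + 1 - sr;
      int f = (H > 1) ? std::min((int)std::floor(sr), H - 1) : 1;
      r0[r] = f - 1;
      wr[r] = sr - f;
    }
    for (int c = 0; c < W; ++c) {
      double sc = reflect1(cc + (c + 1 - cc) / zoom - dx, W);
      if (fh) sc = W + 1 - sc;
      int f = (W > 1) ? std::min((int)std::floor(sc), W - 1) : 1;
      c0[c] = f - 1;
      wc[c] = sc - f;
    }
    for (int ch = 0; ch < C; ++ch) {
      const double* M = im + (size_t)H * W * ch;
      double* O = o + (size_t)H * W * ch;
      const double g = pars(v, 5 + ch), off = pars(v, 5 + C + ch);
      for (int c = 0; c < W; ++c) {
        int cl = c0[c], cu = std::min(cl + 1, W - 1);
        double w = wc[c];
        const double* Ml = M + (size_t)H * cl;
        const double* Mu = M + (size_t)H * cu;
        double* Oc = O + (size_t)H * c;
        for (int r = 0; r < H; ++r) {
          int rl = r0[r], ru = std::min(rl + 1, H - 1);
          double vv = wr[r];
          double val = (1 - vv) * ((1 - w) * Ml[rl] + w * Mu[rl]) +
                       vv * ((1 - w) * Ml[ru] + w * Mu[ru]);
          val = (a * val + b0) * g + off;
          if (val < lo) val = lo;
          if (val > hi) val = hi;
          Oc[r] = val;
        }
      }
    }
  }
  return out;
}
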