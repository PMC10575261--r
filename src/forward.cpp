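// Batched numeric forward pass of the denoiser, used for sampling where no
// gradients are needed. Mirrors the R reference implementation
// (.dsat_forward_num); equality between the two paths is asserted in the
// test suite. B records are stacked record-major as a (B*L) x channels
// matrix.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::cx_mat;
using arma::uvec;

static mat layer_norm(const mat& x, const vec& g, const vec& b, double eps = 1e-5) {
  vec mu = arma::mean(x, 1);
  mat xc = x.each_col() - mu;
  vec inv = 1.0 / arma::sqrt(arma::mean(arma::square(xc), 1) + eps);
  mat xhat = xc.each_col() % inv;
  xhat.each_row() %= g.t();
  xhat.each_row() += b.t();
  return xhat;
}

static mat gelu(const mat& x) { return x / (1.0 + arma::exp(-1.702 * x)); }

static mat sigmoid(const mat& x) { return 1.0 / (1.0 + arma::exp(-x)); }

static mat softmax_rows(const mat& S) {
  mat E = arma::exp(S.each_col() - arma::max(S, 1));
  E.each_col() /= arma::sum(E, 1);
  return E;
}

struct LayerSpec {
  bool global;
  bool banded;
  uvec cells, slots;
  int nb;
  cx_mat fk;        // FFT of the S4 kernels, 2L x d (global layers)
  mat Wq, Wk, Wv, Wo, Wcat, W1, W2;
  vec bo, bcat, b1, b2, ln0_g, ln0_b, lnl_g, lnl_b, lng_g, lng_b, ln2_g, ln2_b;
};

static LayerSpec unpack_layer(const List& sp) {
  LayerSpec s;
  s.global = as<bool>(sp["global"]);
  s.banded = as<bool>(sp["banded"]);
  if (s.banded) {
    s.cells = as<uvec>(sp["cells"]);   // 0-based
    s.slots = as<uvec>(sp["slots"]);
    s.nb = as<int>(sp["nb"]);
  }
  if (s.global) {
    s.fk = as<cx_mat>(sp["fk"]);
    s.lng_g = as<vec>(sp["lng_g"]); s.lng_b = as<vec>(sp["lng_b"]);
  }
  s.Wq = as<mat>(sp["Wq"]); s.Wk = as<mat>(sp["Wk"]); s.Wv = as<mat>(sp["Wv"]);
  s.Wo = as<mat>(sp["Wo"]); s.bo = as<vec>(sp["bo"]);
  s.Wcat = as<mat>(sp["Wcat"]); s.bcat = as<vec>(sp["bcat"]);
  s.W1 = as<mat>(sp["W1"]); s.b1 = as<vec>(sp["b1"]);
  s.W2 = as<mat>(sp["W2"]); s.b2 = as<vec>(sp["b2"]);
  s.ln0_g = as<vec>(sp["ln0_g"]); s.ln0_b = as<vec>(sp["ln0_b"]);
  s.lnl_g = as<vec>(sp["lnl_g"]); s.lnl_b = as<vec>(sp["lnl_b"]);
  s.ln2_g = as<vec>(sp["ln2_g"]); s.ln2_b = as<vec>(sp["ln2_b"]);
  return s;
}

// banded attention in O(L w d): scores and weighted sums touch only the
// |i-j| <= w window; identical to masked-softmax dense attention
static mat attention_banded(const mat& Qh, const mat& Kh, const mat& Vh,
                            int w, double scale) {
  int L = Qh.n_rows, nb = 2 * w + 1;
  mat Qt = Qh.t(), Kt = Kh.t(), Vt = Vh.t();   // columns contiguous
  mat Sb(L, nb);
  Sb.fill(-arma::datum::inf);
  for (int i = 0; i < L; ++i) {
    int j0 = std::max(0, i - w), j1 = std::min(L - 1, i + w);
    for (int j = j0; j <= j1; ++j)
      Sb(i, j - i + w) = arma::dot(Qt.col(i), Kt.col(j)) * scale;
  }
  vec rowmax = arma::max(Sb, 1);
  Sb.each_col() -= rowmax;
  Sb = arma::exp(Sb);                          // exp(-inf) = 0 off the edges
  Sb.each_col() /= arma::sum(Sb, 1);
  mat Ot(Vt.n_rows, L, arma::fill::zeros);
  for (int i = 0; i < L; ++i) {
    int j0 = std::max(0, i - w), j1 = std::min(L - 1, i + w);
    for (int j = j0; j <= j1; ++j)
      Ot.col(i) += Sb(i, j - i + w) * Vt.col(j);
  }
  return Ot.t();
}

static mat attention(const mat& Xn, const LayerSpec& s, int n_heads, int B) {
  int L = Xn.n_rows / B;
  int d = Xn.n_cols;
  int dh = d / n_heads;
  int w = s.banded ? (s.nb - 1) / 2 : 0;
  mat Q = Xn * s.Wq, K = Xn * s.Wk, V = Xn * s.Wv;
  mat O(Xn.n_rows, d, arma::fill::zeros);
  double scale = 1.0 / std::sqrt((double)dh);
  for (int b = 0; b < B; ++b) {
    arma::span rows(b * L, (b + 1) * L - 1);
    for (int h = 0; h < n_heads; ++h) {
      arma::span cols(h * dh, (h + 1) * dh - 1);
      if (s.banded) {
        O(rows, cols) = attention_banded(Q(rows, cols), K(rows, cols),
                                         V(rows, cols), w, scale);
      } else {
        mat S = Q(rows, cols) * K(rows, cols).t() * scale;
        O(rows, cols) = softmax_rows(S) * V(rows, cols);
      }
    }
  }
  O *= s.Wo;
  O.each_row() += s.bo.t();
  return O;
}

// batched causal convolution via FFT; columns channel-major, record fastest
static mat causal_conv(const mat& Xn, const cx_mat& fk, int B) {
  int n = Xn.n_rows, d = Xn.n_cols, L = n / B, m = 2 * L;
  mat Xw(m, B * d, arma::fill::zeros);
  // reshape (B*L) x d -> L x (B*d): column (c*B + b) holds record b, chan c
  for (int c = 0; c < d; ++c)
    for (int b = 0; b < B; ++b)
      Xw.submat(0, c * B + b, L - 1, c * B + b) = Xn.submat(b * L, c, (b + 1) * L - 1, c);
  cx_mat fx = arma::fft(Xw);
  for (int c = 0; c < d; ++c)
    for (int b = 0; b < B; ++b)
      fx.col(c * B + b) %= fk.col(c);
  mat Yw = arma::real(arma::ifft(fx));
  mat Y(n, d);
  for (int c = 0; c < d; ++c)
    for (int b = 0; b < B; ++b)
      Y.submat(b * L, c, (b + 1) * L - 1, c) = Yw.submat(0, c * B + b, L - 1, c * B + b);
  return Y;
}

static mat spade_forward(const mat& X, const LayerSpec& s, int n_heads, int B) {
  mat Xn = layer_norm(X, s.ln0_g, s.ln0_b);
  mat branch = layer_norm(attention(Xn, s, n_heads, B), s.lnl_g, s.lnl_b);
  if (s.global) {
    mat Xg = causal_conv(Xn, s.fk, B);
    branch = arma::join_rows(branch, layer_norm(Xg, s.lng_g, s.lng_b));
  }
  mat Xa = branch * s.Wcat;
  Xa.each_row() += s.bcat.t();
  Xa += X;
  mat H = layer_norm(Xa, s.ln2_g, s.ln2_b);
  mat F1 = H * s.W1;
  F1.each_row() += s.b1.t();
  mat ffn = gelu(F1) * s.W2;
  ffn.each_row() += s.b2.t();
  return ffn + Xa;
}

// [[Rcpp::export(name = ".dsat_forward_cpp")]]
arma::mat dsat_forward_cpp(const List& packed, const arma::mat& X, int t,
                           const arma::mat& cmat, int B) {
  const List P = packed["params"];
  const List blocks = packed["blocks"];
  int n_heads = as<int>(packed["n_heads"]);
  int Cres = as<int>(packed["residual_channels"]);
  int n_blocks = blocks.size();
  int n = X.n_rows, L = n / B;

  // diffusion-step embedding
  vec sinu = as<vec>(packed["sinusoid_base"]);  // frequencies, length d0
  int d0 = sinu.n_elem;
  arma::rowvec e(d0);
  int half = d0 / 2 > 0 ? d0 / 2 : 1;
  for (int j = 0; j < d0; ++j)
    e(j) = (j < half) ? std::sin(t * sinu(j)) : std::cos(t * sinu(j - half));
  mat e1 = e * as<mat>(P["emb.W1"]);
  e1.each_row() += as<vec>(P["emb.b1"]).t();
  e1 = e1 % sigmoid(e1);
  mat emb = e1 * as<mat>(P["emb.W2"]);
  emb.each_row() += as<vec>(P["emb.b2"]).t();
  emb = emb % sigmoid(emb);

  mat h = X * as<mat>(P["in.W"]);
  h.each_row() += as<vec>(P["in.b"]).t();
  h = arma::clamp(h, 0.0, arma::datum::inf);

  bool shared_c = cmat.n_rows == 1;
  mat skip;
  for (int b = 0; b < n_blocks; ++b) {
    const List blk = blocks[b];
    std::string pre = "b" + std::to_string(b + 1) + ".";
    arma::rowvec eb = emb * as<mat>(P[pre + "emb.W"]) + as<vec>(P[pre + "emb.b"]).t();
    mat hb = h;
    hb.each_row() += eb;
    const List sps = blk["layers"];
    for (int j = 0; j < sps.size(); ++j)
      hb = spade_forward(hb, unpack_layer(sps[j]), n_heads, B);
    mat g = hb * as<mat>(P[pre + "gate.W"]);
    g.each_row() += as<vec>(P[pre + "gate.b"]).t();
    mat cb = cmat * as<mat>(P[pre + "cond.W"]);
    cb.each_row() += as<vec>(P[pre + "cond.b"]).t();
    if (shared_c) {
      g.each_row() += cb.row(0);
    } else {
      for (int r = 0; r < B; ++r)
        g.rows(r * L, (r + 1) * L - 1).each_row() += cb.row(r);
    }
    mat z = arma::tanh(g.cols(0, Cres - 1)) % sigmoid(g.cols(Cres, 2 * Cres - 1));
    mat sk = z * as<mat>(P[pre + "skip.W"]);
    sk.each_row() += as<vec>(P[pre + "skip.b"]).t();
    if (b < n_blocks - 1) {
      mat res = z * as<mat>(P[pre + "res.W"]);
      res.each_row() += as<vec>(P[pre + "res.b"]).t();
      h = (h + res) / std::sqrt(2.0);
    }
    skip = (b == 0) ? sk : mat(skip + sk);
  }
  mat s = skip / std::sqrt((double)n_blocks);
  mat cp = cmat * as<mat>(P["post.cond.W"]);
  cp.each_row() += as<vec>(P["post.cond.b"]).t();
  if (shared_c) {
    s.each_row() += cp.row(0);
  } else {
    for (int r = 0; r < B; ++r)
      s.rows(r * L, (r + 1) * L - 1).each_row() += cp.row(r);
  }
  s = spade_forward(s, unpack_layer(packed["post"]), n_heads, B);
  mat out = s * as<mat>(P["out.W1"]);
  out.each_row() += as<vec>(P["out.b1"]).t();
  out = arma::clamp(out, 0.0, arma::datum::inf);
  out = out * as<mat>(P["out.W2"]);
  out.each_row() += as<vec>(P["out.b2"]).t();
  return out;
}
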