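// Small residual convolutional instance scorer: forward, backprop and one
// Adam training epoch over bags, with the two weak-supervision heads
// (max-pooling / MIL against the binary bag label, average-pooling / LLP
// against the metastatic proportion).
//
// Feature maps are stored as C x (H*W) matrices, spatial index s = r*W + c
// (row-major pixels). Patches arrive as rows of an N x (H*W) matrix.
// Convolutions are evaluated as nine shifted GEMMs over a zero-padded
// buffer (with a guard margin so every shift is a contiguous column range),
// which avoids materializing im2col matrices.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::mat;
using arma::vec;

static const int N_PAR = 14;
static const char* PAR_NAMES[N_PAR] = {
  "W0", "b0", "WA1", "bA1", "WA2", "bA2", "W1", "b1",
  "WB1", "bB1", "WB2", "bB2", "wd", "bd"
};

static inline int guardOf(int W) { return W + 3; }

// embed a C x (H*W) map into a zero-padded (H+2)x(W+2) buffer with guard
static mat pad_embed(const mat& X, int H, int W) {
  const int Wp = W + 2, Hp = H + 2, g = guardOf(W);
  mat P(X.n_rows, Hp * Wp + 2 * g, arma::fill::zeros);
  for (int r = 0; r < H; ++r)
    P.cols(g + (r + 1) * Wp + 1, g + (r + 1) * Wp + W) =
      X.cols(r * W, r * W + W - 1);
  return P;
}

// extract the interior H x W region; `off` is the column of padded
// position 0 (the guard width for guarded buffers, 0 otherwise)
static mat pad_extract(const mat& P, int H, int W, int off) {
  const int Wp = W + 2;
  mat X(P.n_rows, H * W);
  for (int r = 0; r < H; ++r)
    X.cols(r * W, r * W + W - 1) =
      P.cols(off + (r + 1) * Wp + 1, off + (r + 1) * Wp + W);
  return X;
}

// 3x3 conv, pad 1, stride 1: interior output from a padded input buffer
static mat conv3(const mat& Wm, const mat& b, const mat& Xpad,
                 int H, int W) {
  const int Wp = W + 2, Hp = H + 2, S = Hp * Wp, g = guardOf(W);
  const int Cin = Xpad.n_rows;
  mat Y(Wm.n_rows, S, arma::fill::zeros); // indexed by padded position
  for (int k = 0; k < 9; ++k) {
    const int off = (k / 3 - 1) * Wp + (k % 3 - 1);
    Y += Wm.cols(k * Cin, (k + 1) * Cin - 1) *
      Xpad.cols(g + off, g + off + S - 1);
  }
  mat out = pad_extract(Y, H, W, 0);
  out.each_col() += b.col(0);
  return out;
}

// gradients of a conv3 layer; dY is the interior gradient. Accumulates gW
// and gb; if dX is non-null, writes the interior input gradient into it.
static void conv3_back(const mat& Wm, mat& gW, mat& gb, const mat& dY,
                       const mat& Xpad, int H, int W, mat* dX) {
  const int Wp = W + 2, Hp = H + 2, S = Hp * Wp, g = guardOf(W);
  const int Cin = Xpad.n_rows;
  mat dYpad = pad_embed(dY, H, W);
  for (int k = 0; k < 9; ++k) {
    const int off = (k / 3 - 1) * Wp + (k % 3 - 1);
    gW.cols(k * Cin, (k + 1) * Cin - 1) +=
      dYpad.cols(g, g + S - 1) *
      arma::trans(Xpad.cols(g + off, g + off + S - 1));
  }
  gb.col(0) += arma::sum(dY, 1);
  if (dX) {
    mat dXp(Cin, S, arma::fill::zeros);
    for (int k = 0; k < 9; ++k) {
      const int off = (k / 3 - 1) * Wp + (k % 3 - 1);
      dXp += arma::trans(Wm.cols(k * Cin, (k + 1) * Cin - 1)) *
        dYpad.cols(g - off, g - off + S - 1);
    }
    *dX = pad_extract(dXp, H, W, 0);
  }
}

// 2x2 max pooling; records the winning source column per channel/output
// position for gradient routing
static mat maxpool2(const mat& A, int H, int W, arma::umat& idx) {
  const int H2 = H / 2, W2 = W / 2;
  const int C = A.n_rows;
  mat P(C, H2 * W2);
  idx.set_size(C, H2 * W2);
  for (int r = 0; r < H2; ++r)
    for (int c = 0; c < W2; ++c) {
      const int s = r * W2 + c;
      const int src[4] = { 2 * r * W + 2 * c, 2 * r * W + 2 * c + 1,
                           (2 * r + 1) * W + 2 * c,
                           (2 * r + 1) * W + 2 * c + 1 };
      for (int ch = 0; ch < C; ++ch) {
        double best = A(ch, src[0]); int bi = src[0];
        for (int q = 1; q < 4; ++q)
          if (A(ch, src[q]) > best) { best = A(ch, src[q]); bi = src[q]; }
        P(ch, s) = best;
        idx(ch, s) = bi;
      }
    }
  return P;
}

// H, W are the dimensions of the pre-pooling map
static mat maxpool2_back(const mat& dP, const arma::umat& idx, int H, int W) {
  mat dA(dP.n_rows, H * W, arma::fill::zeros);
  for (arma::uword s = 0; s < dP.n_cols; ++s)
    for (arma::uword ch = 0; ch < dP.n_rows; ++ch)
      dA(ch, idx(ch, s)) += dP(ch, s);
  return dA;
}

static inline void relu_(mat& X) {
  X.transform([](double v) { return v > 0.0 ? v : 0.0; });
}

struct Net {
  mat W0, b0, WA1, bA1, WA2, bA2, W1, b1, WB1, bB1, WB2, bB2, wd, bd;
  int C0, C1;
  explicit Net(const List& w) {
    W0 = as<mat>(w["W0"]);  b0 = as<mat>(w["b0"]);
    WA1 = as<mat>(w["WA1"]); bA1 = as<mat>(w["bA1"]);
    WA2 = as<mat>(w["WA2"]); bA2 = as<mat>(w["bA2"]);
    W1 = as<mat>(w["W1"]);  b1 = as<mat>(w["b1"]);
    WB1 = as<mat>(w["WB1"]); bB1 = as<mat>(w["bB1"]);
    WB2 = as<mat>(w["WB2"]); bB2 = as<mat>(w["bB2"]);
    wd = as<mat>(w["wd"]);  bd = as<mat>(w["bd"]);
    C0 = W0.n_rows; C1 = W1.n_rows;
  }
  mat* par(int i) {
    mat* p[N_PAR] = { &W0, &b0, &WA1, &bA1, &WA2, &bA2, &W1, &b1,
                      &WB1, &bB1, &WB2, &bB2, &wd, &bd };
    return p[i];
  }
  List toList() {
    List out(N_PAR);
    CharacterVector nm(N_PAR);
    for (int i = 0; i < N_PAR; ++i) { out[i] = *par(i); nm[i] = PAR_NAMES[i]; }
    out.attr("names") = nm;
    return out;
  }
};

struct Cache {
  mat Xpad, A0, P1, P1pad, U, Upad, R1, R1pad, A1, P2, P2pad, U2, U2pad, R2;
  arma::umat I1, I2; // max-pool routing indices
  vec g;
  double z;
};

static double forward(const Net& n, const double* xptr, int H, int W,
                      Cache& c) {
  const int H2 = H / 2, W2 = W / 2, H4 = H / 4, W4 = W / 4;
  mat X0(1, H * W);
  std::memcpy(X0.memptr(), xptr, H * W * sizeof(double));
  c.Xpad = pad_embed(X0, H, W);
  c.A0 = conv3(n.W0, n.b0, c.Xpad, H, W); relu_(c.A0);
  c.P1 = maxpool2(c.A0, H, W, c.I1);
  c.P1pad = pad_embed(c.P1, H2, W2);
  c.U = conv3(n.WA1, n.bA1, c.P1pad, H2, W2); relu_(c.U);
  c.Upad = pad_embed(c.U, H2, W2);
  c.R1 = c.P1 + conv3(n.WA2, n.bA2, c.Upad, H2, W2); relu_(c.R1);
  c.R1pad = pad_embed(c.R1, H2, W2);
  c.A1 = conv3(n.W1, n.b1, c.R1pad, H2, W2); relu_(c.A1);
  c.P2 = maxpool2(c.A1, H2, W2, c.I2);
  c.P2pad = pad_embed(c.P2, H4, W4);
  c.U2 = conv3(n.WB1, n.bB1, c.P2pad, H4, W4); relu_(c.U2);
  c.U2pad = pad_embed(c.U2, H4, W4);
  c.R2 = c.P2 + conv3(n.WB2, n.bB2, c.U2pad, H4, W4); relu_(c.R2);
  c.g = arma::mean(c.R2, 1);
  c.z = arma::dot(n.wd.col(0), c.g) + n.bd(0, 0);
  return c.z;
}

struct Grads {
  mat W0, b0, WA1, bA1, WA2, bA2, W1, b1, WB1, bB1, WB2, bB2, wd, bd;
  explicit Grads(const Net& n) {
    W0.zeros(arma::size(n.W0));   b0.zeros(arma::size(n.b0));
    WA1.zeros(arma::size(n.WA1)); bA1.zeros(arma::size(n.bA1));
    WA2.zeros(arma::size(n.WA2)); bA2.zeros(arma::size(n.bA2));
    W1.zeros(arma::size(n.W1));   b1.zeros(arma::size(n.b1));
    WB1.zeros(arma::size(n.WB1)); bB1.zeros(arma::size(n.bB1));
    WB2.zeros(arma::size(n.WB2)); bB2.zeros(arma::size(n.bB2));
    wd.zeros(arma::size(n.wd));   bd.zeros(arma::size(n.bd));
  }
  mat* par(int i) {
    mat* p[N_PAR] = { &W0, &b0, &WA1, &bA1, &WA2, &bA2, &W1, &b1,
                      &WB1, &bB1, &WB2, &bB2, &wd, &bd };
    return p[i];
  }
};

static void backward(const Net& n, const Cache& c, double dz, int H, int W,
                     Grads& g) {
  const int H2 = H / 2, W2 = W / 2, H4 = H / 4, W4 = W / 4;
  const int S2 = H4 * W4;
  g.wd.col(0) += dz * c.g;
  g.bd(0, 0) += dz;
  mat dR2(n.C1, S2);
  dR2.each_col() = n.wd.col(0) * (dz / S2);
  dR2 %= arma::conv_to<mat>::from(c.R2 > 0.0);
  // residual block B
  mat dU2;
  conv3_back(n.WB2, g.WB2, g.bB2, dR2, c.U2pad, H4, W4, &dU2);
  dU2 %= arma::conv_to<mat>::from(c.U2 > 0.0);
  mat dP2c;
  conv3_back(n.WB1, g.WB1, g.bB1, dU2, c.P2pad, H4, W4, &dP2c);
  mat dP2 = dR2 + dP2c; // skip connection
  // downsampling conv stage
  mat dA1 = maxpool2_back(dP2, c.I2, H2, W2);
  dA1 %= arma::conv_to<mat>::from(c.A1 > 0.0);
  mat dR1;
  conv3_back(n.W1, g.W1, g.b1, dA1, c.R1pad, H2, W2, &dR1);
  dR1 %= arma::conv_to<mat>::from(c.R1 > 0.0);
  // residual block A
  mat dU;
  conv3_back(n.WA2, g.WA2, g.bA2, dR1, c.Upad, H2, W2, &dU);
  dU %= arma::conv_to<mat>::from(c.U > 0.0);
  mat dP1c;
  conv3_back(n.WA1, g.WA1, g.bA1, dU, c.P1pad, H2, W2, &dP1c);
  mat dP1 = dR1 + dP1c;
  // stem
  mat dA0 = maxpool2_back(dP1, c.I1, H, W);
  dA0 %= arma::conv_to<mat>::from(c.A0 > 0.0);
  conv3_back(n.W0, g.W0, g.b0, dA0, c.Xpad, H, W, nullptr);
}

static inline double sigm(double z) { return 1.0 / (1.0 + std::exp(-z)); }

static inline double bce(double p, double t) {
  const double eps = 1e-7;
  p = std::min(std::max(p, eps), 1.0 - eps);
  return -(t * std::log(p) + (1.0 - t) * std::log(1.0 - p));
}

static void check_dims(int H, int W) {
  if (H < 8 || W < 8 || H % 4 != 0 || W % 4 != 0)
    stop("patch side must be >= 8 and divisible by 4");
}

// [[Rcpp::export(name = ".net_logits_cpp")]]
arma::vec net_logits_cpp(List w, const arma::mat& X, int H, int W) {
  check_dims(H, W);
  if ((int)X.n_cols != H * W) stop("patch matrix has wrong number of pixels");
  Net n(w);
  const int N = X.n_rows;
  vec out(N);
  Cache c;
  mat Xt = X.t(); // columns contiguous per patch
  for (int i = 0; i < N; ++i) out(i) = forward(n, Xt.colptr(i), H, W, c);
  return out;
}

// Last convolutional feature maps (output of the final residual block) and
// the analytic gradient of the logit w.r.t. them: d z / d R2[c, s] = wd_c / S
// [[Rcpp::export(name = ".net_maps_cpp")]]
List net_maps_cpp(List w, const arma::vec& x, int H, int W) {
  check_dims(H, W);
  Net n(w);
  Cache c;
  forward(n, x.memptr(), H, W, c);
  const int S2 = (H / 4) * (W / 4);
  mat grad(n.C1, S2);
  grad.each_col() = n.wd.col(0) / (double)S2;
  return List::create(_["maps"] = c.R2, _["grad"] = grad,
                      _["H4"] = H / 4, _["W4"] = W / 4, _["logit"] = c.z);
}

// Loss and raw (unclipped) weight gradients for a single bag; used by the
// finite-difference gradient checks.
// [[Rcpp::export(name = ".net_bag_grad_cpp")]]
List net_bag_grad_cpp(List w, const arma::mat& X, double y, double rho,
                      double lambdaMil, double lambdaLlp, int H, int W) {
  check_dims(H, W);
  Net n(w);
  mat Xt = X.t();
  const int len = X.n_rows;
  std::vector<Cache> caches(len);
  vec p(len);
  int imax = 0;
  for (int i = 0; i < len; ++i) {
    forward(n, Xt.colptr(i), H, W, caches[i]);
    p(i) = sigm(caches[i].z);
    if (p(i) > p(imax)) imax = i;
  }
  const double pmax = p(imax);
  const double pavg = arma::mean(p);
  const double loss = lambdaMil * bce(pmax, y) + lambdaLlp * bce(pavg, rho);
  vec dz(len, arma::fill::zeros);
  if (lambdaMil > 0.0) dz(imax) += lambdaMil * (pmax - y);
  if (lambdaLlp > 0.0) {
    const double denom = std::max(pavg * (1.0 - pavg), 1e-12);
    const double common = lambdaLlp * (pavg - rho) / denom / (double)len;
    for (int i = 0; i < len; ++i) dz(i) += common * p(i) * (1.0 - p(i));
  }
  Grads g(n);
  for (int i = 0; i < len; ++i)
    if (dz(i) != 0.0) backward(n, caches[i], dz(i), H, W, g);
  List gOut(N_PAR);
  CharacterVector nm(N_PAR);
  for (int i = 0; i < N_PAR; ++i) { gOut[i] = *g.par(i); nm[i] = PAR_NAMES[i]; }
  gOut.attr("names") = nm;
  return List::create(_["loss"] = loss, _["grads"] = gOut,
                      _["probs"] = p);
}

// One epoch of bag-wise Adam training under the two weak-supervision heads.
// bagStart/bagLen are 0-based row offsets into X; order is the (0-based)
// visiting order of bags; y and rho are per-bag targets.
// [[Rcpp::export(name = ".net_train_epoch_cpp")]]
List net_train_epoch_cpp(List w, List m, List v, int t,
                         const arma::mat& X,
                         IntegerVector bagStart, IntegerVector bagLen,
                         IntegerVector order,
                         NumericVector y, NumericVector rho,
                         double lambdaMil, double lambdaLlp,
                         double lr, double beta1, double beta2,
                         double adamEps, double clip, int H, int W) {
  check_dims(H, W);
  Net n(w);
  std::vector<mat> M(N_PAR), V(N_PAR);
  for (int i = 0; i < N_PAR; ++i) {
    M[i] = as<mat>(m[PAR_NAMES[i]]);
    V[i] = as<mat>(v[PAR_NAMES[i]]);
  }
  mat Xt = X.t();
  const int nBags = order.size();
  double totLoss = 0.0;
  for (int ob = 0; ob < nBags; ++ob) {
    const int b = order[ob];
    const int start = bagStart[b], len = bagLen[b];
    std::vector<Cache> caches(len);
    vec p(len);
    int imax = 0;
    for (int i = 0; i < len; ++i) {
      forward(n, Xt.colptr(start + i), H, W, caches[i]);
      p(i) = sigm(caches[i].z);
      if (p(i) > p(imax)) imax = i;
    }
    const double pmax = p(imax);
    const double pavg = arma::mean(p);
    totLoss += lambdaMil * bce(pmax, y[b]) + lambdaLlp * bce(pavg, rho[b]);
    vec dz(len, arma::fill::zeros);
    if (lambdaMil > 0.0) dz(imax) += lambdaMil * (pmax - y[b]);
    if (lambdaLlp > 0.0) {
      const double denom = std::max(pavg * (1.0 - pavg), 1e-12);
      const double common = lambdaLlp * (pavg - rho[b]) / denom / (double)len;
      for (int i = 0; i < len; ++i) dz(i) += common * p(i) * (1.0 - p(i));
    }
    Grads g(n);
    for (int i = 0; i < len; ++i)
      if (dz(i) != 0.0) backward(n, caches[i], dz(i), H, W, g);
    // global gradient-norm clipping
    double sq = 0.0;
    for (int i = 0; i < N_PAR; ++i) sq += arma::accu(*g.par(i) % *g.par(i));
    const double nrm = std::sqrt(sq);
    if (clip > 0.0 && nrm > clip) {
      const double sc = clip / nrm;
      for (int i = 0; i < N_PAR; ++i) (*g.par(i)) *= sc;
    }
    // Adam step
    ++t;
    const double bc1 = 1.0 - std::pow(beta1, t);
    const double bc2 = 1.0 - std::pow(beta2, t);
    for (int i = 0; i < N_PAR; ++i) {
      mat& gi = *g.par(i);
      M[i] = beta1 * M[i] + (1.0 - beta1) * gi;
      V[i] = beta2 * V[i] + (1.0 - beta2) * (gi % gi);
      *n.par(i) -= lr * (M[i] / bc1) / (arma::sqrt(V[i] / bc2) + adamEps);
    }
  }
  List mOut(N_PAR), vOut(N_PAR);
  CharacterVector nm(N_PAR);
  for (int i = 0; i < N_PAR; ++i) {
    mOut[i] = M[i]; vOut[i] = V[i]; nm[i] = PAR_NAMES[i];
  }
  mOut.attr("names") = nm;
  vOut.attr("names") = nm;
  return List::create(_["w"] = n.toList(), _["m"] = mOut, _["v"] = vOut,
                      _["t"] = t, _["loss"] = totLoss / std::max(nBags, 1));
}
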