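// U-Net segmentation engine: 3x3 stride-1 convolutions with batch
// normalization and ReLU, 2x2 max pooling on the encoder path, stride-2
// 2x2 transpose convolutions with concatenating skip connections on the
// decoder path, and a final 1x1 convolution with sigmoid output. Trained
// with dice loss and Adam. Activations are stored as (channels x
// height*width*batch) matrices so convolutions reduce to im2col GEMMs.
#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::umat;
using arma::uvec;

static const double BN_EPS = 1e-5;
static const double BN_MOMENTUM = 0.1;

// ---------------------------------------------------------------------------
// im2col / col2im for 3x3 same-padding convolution.
// Activation layout: column j = b*H*W + c*H + r (column-major per image).
static mat im2col3(const mat &A, int H, int W, int B) {
  const int C = A.n_rows;
  const int HW = H * W;
  mat X(9 * C, A.n_cols, arma::fill::zeros);
  for (int dc = -1; dc <= 1; ++dc) {
    for (int dr = -1; dr <= 1; ++dr) {
      const int dIdx = (dc + 1) * 3 + (dr + 1);
      const int r_lo = std::max(0, -dr);
      const int r_hi = std::min(H, H - dr); // dst rows with valid src
      if (r_hi <= r_lo) continue;
      for (int b = 0; b < B; ++b) {
        for (int c0 = 0; c0 < W; ++c0) {
          const int cs = c0 + dc;
          if (cs < 0 || cs >= W) continue;
          const int dst = b * HW + c0 * H + r_lo;
          const int src = b * HW + cs * H + r_lo + dr;
          const int len = r_hi - r_lo;
          X.submat(dIdx * C, dst, (dIdx + 1) * C - 1, dst + len - 1) =
              A.cols(src, src + len - 1);
        }
      }
    }
  }
  return X;
}

static mat col2im3(const mat &Xcol, int H, int W, int B, int C) {
  const int HW = H * W;
  mat A(C, Xcol.n_cols, arma::fill::zeros);
  for (int dc = -1; dc <= 1; ++dc) {
    for (int dr = -1; dr <= 1; ++dr) {
      const int dIdx = (dc + 1) * 3 + (dr + 1);
      const int r_lo = std::max(0, -dr);
      const int r_hi = std::min(H, H - dr);
      if (r_hi <= r_lo) continue;
      for (int b = 0; b < B; ++b) {
        for (int c0 = 0; c0 < W; ++c0) {
          const int cs = c0 + dc;
          if (cs < 0 || cs >= W) continue;
          const int dst = b * HW + c0 * H + r_lo;
          const int src = b * HW + cs * H + r_lo + dr;
          const int len = r_hi - r_lo;
          A.cols(src, src + len - 1) +=
              Xcol.submat(dIdx * C, dst, (dIdx + 1) * C - 1, dst + len - 1);
        }
      }
    }
  }
  return A;
}

// ---------------------------------------------------------------------------
// Adam state for a single parameter tensor.
struct Param {
  mat val, g, m, v;
  void init(int r, int c) {
    val.zeros(r, c); g.zeros(r, c); m.zeros(r, c); v.zeros(r, c);
  }
  void step(double lr, long t) {
    const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
    m = b1 * m + (1 - b1) * g;
    v = b2 * v + (1 - b2) * arma::square(g);
    mat mhat = m / (1 - std::pow(b1, (double)t));
    mat vhat = v / (1 - std::pow(b2, (double)t));
    val -= lr * mhat / (arma::sqrt(vhat) + eps);
  }
};

// conv 3x3 + batch norm + ReLU
struct ConvBlock {
  int cin = 0, cout = 0;
  Param W, b, gamma, beta;
  vec rmean, rvar;
  // caches
  mat Xcol, xhat, relu_out;
  vec bsd;
  int H = 0, Wd = 0, B = 0;

  void init(int cin_, int cout_, std::mt19937 &rng) {
    cin = cin_; cout = cout_;
    W.init(cout, 9 * cin); b.init(cout, 1);
    gamma.init(cout, 1); beta.init(cout, 1);
    gamma.val.ones();
    rmean.zeros(cout); rvar.ones(cout);
    std::normal_distribution<double> nd(0.0, std::sqrt(2.0 / (9.0 * cin)));
    for (auto &w : W.val) w = nd(rng);
  }

  mat forward(const mat &A, int H_, int W_, int B_, bool train) {
    H = H_; Wd = W_; B = B_;
    Xcol = im2col3(A, H, Wd, B);
    mat Y = W.val * Xcol;
    Y.each_col() += b.val.col(0);
    vec mu, var_;
    if (train) {
      mu = arma::mean(Y, 1);
      mat cent = Y.each_col() - mu;
      var_ = arma::mean(arma::square(cent), 1);
      bsd = arma::sqrt(var_ + BN_EPS);
      xhat = cent.each_col() / bsd;
      rmean = (1 - BN_MOMENTUM) * rmean + BN_MOMENTUM * mu;
      rvar = (1 - BN_MOMENTUM) * rvar + BN_MOMENTUM * var_;
    } else {
      bsd = arma::sqrt(rvar + BN_EPS);
      xhat = (Y.each_col() - rmean).each_col() / bsd;
    }
    mat Z = xhat.each_col() % gamma.val.col(0);
    Z.each_col() += beta.val.col(0);
    relu_out = arma::clamp(Z, 0.0, arma::datum::inf);
    return relu_out;
  }

  mat backward(const mat &dOut) {
    mat dZ = dOut;
    dZ.elem(arma::find(relu_out <= 0)).zeros();
    const double n = (double)dZ.n_cols;
    gamma.g = arma::sum(dZ % xhat, 1);
    beta.g = arma::sum(dZ, 1);
    mat dxhat = dZ.each_col() % gamma.val.col(0);
    vec s1 = arma::sum(dxhat, 1) / n;
    vec s2 = arma::sum(dxhat % xhat, 1) / n;
    mat dY = dxhat;
    dY.each_col() -= s1;
    dY -= xhat.each_col() % s2;
    dY.each_col() /= bsd;
    W.g = dY * Xcol.t();
    b.g = arma::sum(dY, 1);
    return col2im3(W.val.t() * dY, H, Wd, B, cin);
  }
};

// stride-2 2x2 transpose convolution (exact 2x upsampling, no overlap),
// followed by batch normalization and ReLU like every other convolution.
struct UpBlock {
  int cin = 0, cout = 0;
  Param W, b, gamma, beta; // W: (4*cout, cin)
  vec rmean, rvar;
  mat Xin, xhat, relu_out;
  vec bsd;
  int Hi = 0, Wi = 0, B = 0;

  void init(int cin_, int cout_, std::mt19937 &rng) {
    cin = cin_; cout = cout_;
    W.init(4 * cout, cin); b.init(cout, 1);
    gamma.init(cout, 1); beta.init(cout, 1);
    gamma.val.ones();
    rmean.zeros(cout); rvar.ones(cout);
    std::normal_distribution<double> nd(0.0, std::sqrt(2.0 / cin));
    for (auto &w : W.val) w = nd(rng);
  }

  mat forward(const mat &A, int Hi_, int Wi_, int B_, bool train) {
    Hi = Hi_; Wi = Wi_; B = B_;
    Xin = A;
    mat Z = W.val * A;
    const int HWi = Hi * Wi, Ho = 2 * Hi;
    mat Y(cout, 4 * A.n_cols);
    for (int bb = 0; bb < B; ++bb) {
      for (int c0 = 0; c0 < Wi; ++c0) {
        for (int r0 = 0; r0 < Hi; ++r0) {
          const int incol = bb * HWi + c0 * Hi + r0;
          for (int dc = 0; dc < 2; ++dc) {
            for (int dr = 0; dr < 2; ++dr) {
              const int dpos = dc * 2 + dr;
              const int outcol =
                  bb * 4 * HWi + (2 * c0 + dc) * Ho + (2 * r0 + dr);
              Y.col(outcol) =
                  Z.rows(dpos * cout, (dpos + 1) * cout - 1).col(incol) +
                  b.val.col(0);
            }
          }
        }
      }
    }
    vec mu, var_;
    if (train) {
      mu = arma::mean(Y, 1);
      mat cent = Y.each_col() - mu;
      var_ = arma::mean(arma::square(cent), 1);
      bsd = arma::sqrt(var_ + BN_EPS);
      xhat = cent.each_col() / bsd;
      rmean = (1 - BN_MOMENTUM) * rmean + BN_MOMENTUM * mu;
      rvar = (1 - BN_MOMENTUM) * rvar + BN_MOMENTUM * var_;
    } else {
      bsd = arma::sqrt(rvar + BN_EPS);
      xhat = (Y.each_col() - rmean).each_col() / bsd;
    }
    mat O = xhat.each_col() % gamma.val.col(0);
    O.each_col() += beta.val.col(0);
    relu_out = arma::clamp(O, 0.0, arma::datum::inf);
    return relu_out;
  }

  mat backward(const mat &dOut) {
    mat dO = dOut;
    dO.elem(arma::find(relu_out <= 0)).zeros();
    const double n = (double)dO.n_cols;
    gamma.g = arma::sum(dO % xhat, 1);
    beta.g = arma::sum(dO, 1);
    mat dxhat = dO.each_col() % gamma.val.col(0);
    vec s1 = arma::sum(dxhat, 1) / n;
    vec s2 = arma::sum(dxhat % xhat, 1) / n;
    mat dY = dxhat;
    dY.each_col() -= s1;
    dY -= xhat.each_col() % s2;
    dY.each_col() /= bsd;

    const int HWi = Hi * Wi, Ho = 2 * Hi;
    mat dZ(4 * cout, Xin.n_cols, arma::fill::zeros);
    b.g.zeros(cout, 1);
    for (int bb = 0; bb < B; ++bb) {
      for (int c0 = 0; c0 < Wi; ++c0) {
        for (int r0 = 0; r0 < Hi; ++r0) {
          const int incol = bb * HWi + c0 * Hi + r0;
          for (int dc = 0; dc < 2; ++dc) {
            for (int dr = 0; dr < 2; ++dr) {
              const int dpos = dc * 2 + dr;
              const int outcol =
                  bb * 4 * HWi + (2 * c0 + dc) * Ho + (2 * r0 + dr);
              dZ.submat(dpos * cout, incol, (dpos + 1) * cout - 1, incol) =
                  dY.col(outcol);
              b.g += dY.col(outcol);
            }
          }
        }
      }
    }
    W.g = dZ * Xin.t();
    return W.val.t() * dZ;
  }
};

// final 1x1 convolution + sigmoid
struct FinalBlock {
  int cin = 0;
  Param W, b; // (1, cin), (1, 1)
  mat Ain, P;

  void init(int cin_, std::mt19937 &rng) {
    cin = cin_;
    W.init(1, cin); b.init(1, 1);
    std::normal_distribution<double> nd(0.0, std::sqrt(1.0 / cin));
    for (auto &w : W.val) w = nd(rng);
    // class-prior bias: start the sigmoid near the foreground fraction of a
    // ventricle slice (~3%) so early training is not dominated by the
    // background correction on imbalanced masks
    b.val(0, 0) = std::log(0.03 / 0.97);
  }

  mat forward(const mat &A) {
    Ain = A;
    mat Y = W.val * A;
    Y += b.val(0, 0);
    P = 1.0 / (1.0 + arma::exp(-Y));
    return P;
  }

  mat backward(const mat &dP) {
    mat dY = dP % P % (1.0 - P);
    W.g = dY * Ain.t();
    b.g = mat(1, 1, arma::fill::value(arma::accu(dY)));
    return W.val.t() * dY;
  }
};

static mat maxpool2(const mat &A, int H, int W, int B, umat &argmax) {
  const int C = A.n_rows, Ho = H / 2, Wo = W / 2;
  const int HW = H * W, HWo = Ho * Wo;
  mat out(C, (arma::uword)HWo * B);
  argmax.set_size(C, (arma::uword)HWo * B);
  for (int bb = 0; bb < B; ++bb) {
    for (int co = 0; co < Wo; ++co) {
      for (int ro = 0; ro < Ho; ++ro) {
        const int oc = bb * HWo + co * Ho + ro;
        const int base = bb * HW + (2 * co) * H + 2 * ro;
        const int cand[4] = {base, base + 1, base + H, base + H + 1};
        for (int ch = 0; ch < C; ++ch) {
          double best = A(ch, cand[0]);
          int bi = cand[0];
          for (int k = 1; k < 4; ++k) {
            if (A(ch, cand[k]) > best) { best = A(ch, cand[k]); bi = cand[k]; }
          }
          out(ch, oc) = best;
          argmax(ch, oc) = bi;
        }
      }
    }
  }
  return out;
}

static mat maxpool2_backward(const mat &dOut, const umat &argmax,
                             arma::uword in_cols) {
  mat dA(dOut.n_rows, in_cols, arma::fill::zeros);
  for (arma::uword j = 0; j < dOut.n_cols; ++j) {
    for (arma::uword ch = 0; ch < dOut.n_rows; ++ch) {
      dA(ch, argmax(ch, j)) += dOut(ch, j);
    }
  }
  return dA;
}

// ---------------------------------------------------------------------------
struct UNet {
  int L = 0;
  std::vector<int> widths;
  std::vector<ConvBlock> enc;  // 2 per level
  std::vector<ConvBlock> dec;  // 2 per decoder level (L-1 levels)
  std::vector<UpBlock> ups;    // L-1
  FinalBlock fin;
  // forward caches
  std::vector<mat> skips;
  std::vector<umat> pool_idx;
  std::vector<arma::uword> pool_incols;

  void build(const std::vector<int> &w, int seed) {
    widths = w; L = (int)w.size();
    std::mt19937 rng((unsigned)seed);
    enc.resize(2 * L);
    for (int l = 0; l < L; ++l) {
      int cin = (l == 0) ? 1 : w[l - 1];
      enc[2 * l].init(cin, w[l], rng);
      enc[2 * l + 1].init(w[l], w[l], rng);
    }
    ups.resize(L - 1);
    dec.resize(2 * (L - 1));
    for (int i = 0; i < L - 1; ++i) {
      int l = L - 2 - i; // decoder target level
      ups[i].init(w[l + 1], w[l], rng);
      dec[2 * i].init(2 * w[l], w[l], rng);
      dec[2 * i + 1].init(w[l], w[l], rng);
    }
    fin.init(w[0], rng);
  }

  mat forward(const mat &X0, int H, int W, int B, bool train) {
    skips.assign(L - 1, mat());
    pool_idx.assign(L - 1, umat());
    pool_incols.assign(L - 1, 0);
    mat A = X0;
    int h = H, w_ = W;
    for (int l = 0; l < L; ++l) {
      A = enc[2 * l].forward(A, h, w_, B, train);
      A = enc[2 * l + 1].forward(A, h, w_, B, train);
      if (l < L - 1) {
        skips[l] = A;
        pool_incols[l] = A.n_cols;
        A = maxpool2(A, h, w_, B, pool_idx[l]);
        h /= 2; w_ /= 2;
      }
    }
    for (int i = 0; i < L - 1; ++i) {
      int l = L - 2 - i;
      mat up = ups[i].forward(A, h, w_, B, train);
      h *= 2; w_ *= 2;
      A = arma::join_cols(skips[l], up);
      A = dec[2 * i].forward(A, h, w_, B, train);
      A = dec[2 * i + 1].forward(A, h, w_, B, train);
    }
    return fin.forward(A);
  }

  void backward(const mat &dP, int H, int W, int B) {
    mat dA = fin.backward(dP);
    int h = H, w_ = W;
    std::vector<mat> dskips(L - 1);
    for (int i = L - 2; i >= 0; --i) {
      int l = L - 2 - i;
      dA = dec[2 * i + 1].backward(dA);
      dA = dec[2 * i].backward(dA);
      int wl = widths[l];
      dskips[l] = dA.rows(0, wl - 1);
      mat dup = dA.rows(wl, 2 * wl - 1);
      dA = ups[i].backward(dup);
      h /= 2; w_ /= 2;
    }
    // dA now sits at the bottleneck resolution
    for (int l = L - 1; l >= 0; --l) {
      if (l < L - 1) {
        dA = maxpool2_backward(dA, pool_idx[l], pool_incols[l]);
        dA += dskips[l];
        h *= 2; w_ *= 2;
      }
      dA = enc[2 * l + 1].backward(dA);
      dA = enc[2 * l].backward(dA);
    }
  }

  void adam_all(double lr, long t) {
    for (auto &c : enc) { c.W.step(lr, t); c.b.step(lr, t);
                          c.gamma.step(lr, t); c.beta.step(lr, t); }
    for (auto &c : dec) { c.W.step(lr, t); c.b.step(lr, t);
                          c.gamma.step(lr, t); c.beta.step(lr, t); }
    for (auto &u : ups) { u.W.step(lr, t); u.b.step(lr, t);
                          u.gamma.step(lr, t); u.beta.step(lr, t); }
    fin.W.step(lr, t); fin.b.step(lr, t);
  }
};

// ---------------------------------------------------------------------------
// parameter (de)serialization: fixed enumeration order with stable names

static void push_conv(List &out, const ConvBlock &c, const std::string &nm) {
  out[nm + "_W"] = wrap(c.W.val);
  out[nm + "_b"] = wrap(vec(c.b.val.col(0)));
  out[nm + "_gamma"] = wrap(vec(c.gamma.val.col(0)));
  out[nm + "_beta"] = wrap(vec(c.beta.val.col(0)));
  out[nm + "_rmean"] = wrap(c.rmean);
  out[nm + "_rvar"] = wrap(c.rvar);
}

static void pull_conv(const List &in, ConvBlock &c, const std::string &nm) {
  c.W.val = as<mat>(in[nm + "_W"]);
  c.b.val = as<vec>(in[nm + "_b"]);
  c.gamma.val = as<vec>(in[nm + "_gamma"]);
  c.beta.val = as<vec>(in[nm + "_beta"]);
  c.rmean = as<vec>(in[nm + "_rmean"]);
  c.rvar = as<vec>(in[nm + "_rvar"]);
}

static std::string enc_name(int l, int j) {
  return "enc" + std::to_string(l + 1) + "_conv" + std::to_string(j + 1);
}
static std::string dec_name(int i, int j) {
  return "dec" + std::to_string(i + 1) + "_conv" + std::to_string(j + 1);
}

static List net_to_list(const UNet &net) {
  List out;
  for (int l = 0; l < net.L; ++l) {
    push_conv(out, net.enc[2 * l], enc_name(l, 0));
    push_conv(out, net.enc[2 * l + 1], enc_name(l, 1));
  }
  for (int i = 0; i < net.L - 1; ++i) {
    std::string nm = "up" + std::to_string(i + 1);
    out[nm + "_W"] = wrap(net.ups[i].W.val);
    out[nm + "_b"] = wrap(vec(net.ups[i].b.val.col(0)));
    out[nm + "_gamma"] = wrap(vec(net.ups[i].gamma.val.col(0)));
    out[nm + "_beta"] = wrap(vec(net.ups[i].beta.val.col(0)));
    out[nm + "_rmean"] = wrap(net.ups[i].rmean);
    out[nm + "_rvar"] = wrap(net.ups[i].rvar);
    push_conv(out, net.dec[2 * i], dec_name(i, 0));
    push_conv(out, net.dec[2 * i + 1], dec_name(i, 1));
  }
  out["final_W"] = wrap(net.fin.W.val);
  out["final_b"] = wrap(vec(net.fin.b.val.col(0)));
  return out;
}

static void list_to_net(const List &in, UNet &net,
                        const std::vector<int> &widths) {
  net.build(widths, 0); // sizes; weights overwritten below
  for (int l = 0; l < net.L; ++l) {
    pull_conv(in, net.enc[2 * l], enc_name(l, 0));
    pull_conv(in, net.enc[2 * l + 1], enc_name(l, 1));
  }
  for (int i = 0; i < net.L - 1; ++i) {
    std::string nm = "up" + std::to_string(i + 1);
    net.ups[i].W.val = as<mat>(in[nm + "_W"]);
    net.ups[i].b.val = as<vec>(in[nm + "_b"]);
    net.ups[i].gamma.val = as<vec>(in[nm + "_gamma"]);
    net.ups[i].beta.val = as<vec>(in[nm + "_beta"]);
    net.ups[i].rmean = as<vec>(in[nm + "_rmean"]);
    net.ups[i].rvar = as<vec>(in[nm + "_rvar"]);
    pull_conv(in, net.dec[2 * i], dec_name(i, 0));
    pull_conv(in, net.dec[2 * i + 1], dec_name(i, 1));
  }
  net.fin.W.val = as<mat>(in["final_W"]);
  net.fin.b.val = as<vec>(in["final_b"]);
}

static std::vector<int> widths_vec(const IntegerVector &w) {
  std::vector<int> out(w.begin(), w.end());
  if (out.size() < 2) stop("need at least two resolution levels");
  return out;
}

// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List unet_init_cpp(IntegerVector widths, int seed) {
  UNet net;
  net.build(widths_vec(widths), seed);
  return net_to_list(net);
}

// [[Rcpp::export]]
arma::cube unet_forward_cpp(List params, IntegerVector widths, arma::cube X,
                            bool train = false) {
  UNet net;
  list_to_net(params, net, widths_vec(widths));
  const int H = X.n_rows, W = X.n_cols, B = X.n_slices;
  mat X0(arma::vectorise(X).t());
  mat P = net.forward(X0, H, W, B, train);
  return arma::cube(P.memptr(), H, W, B);
}

// Mean over the batch of per-map dice losses: each segmented map is
// compared with its own labeled reference, then losses are averaged.
static double dice_loss_grad(const mat &P, const mat &G, double eps, int B,
                             mat &dP) {
  const arma::uword HW = P.n_cols / B;
  dP.set_size(P.n_rows, P.n_cols);
  double loss = 0;
  for (int b = 0; b < B; ++b) {
    const arma::uword c0 = (arma::uword)b * HW, c1 = c0 + HW - 1;
    const mat Pb = P.cols(c0, c1), Gb = G.cols(c0, c1);
    const double S = arma::accu(Pb % Gb);
    const double D = arma::accu(Pb) + arma::accu(Gb) + eps;
    const double num = 2.0 * S + eps;
    dP.cols(c0, c1) = -(2.0 * Gb * D - num) / (D * D) / B;
    loss += 1.0 - num / D;
  }
  return loss / B;
}

static void push_grads(List &out, const ConvBlock &c, const std::string &nm) {
  out[nm + "_W"] = wrap(c.W.g);
  out[nm + "_b"] = wrap(vec(c.b.g.col(0)));
  out[nm + "_gamma"] = wrap(vec(c.gamma.g.col(0)));
  out[nm + "_beta"] = wrap(vec(c.beta.g.col(0)));
}

// Analytic gradient of the dice loss w.r.t. every trainable parameter, for
// finite-difference verification of the backward pass.
// [[Rcpp::export]]
List unet_grad_cpp(List params, IntegerVector widths, arma::cube X,
                   arma::cube Y, double dice_eps) {
  UNet net;
  list_to_net(params, net, widths_vec(widths));
  const int H = X.n_rows, W = X.n_cols, B = X.n_slices;
  mat X0(arma::vectorise(X).t());
  mat G0(arma::vectorise(Y).t());
  mat P = net.forward(X0, H, W, B, true);
  mat dP;
  double loss = dice_loss_grad(P, G0, dice_eps, B, dP);
  net.backward(dP, H, W, B);
  List out;
  for (int l = 0; l < net.L; ++l) {
    push_grads(out, net.enc[2 * l], enc_name(l, 0));
    push_grads(out, net.enc[2 * l + 1], enc_name(l, 1));
  }
  for (int i = 0; i < net.L - 1; ++i) {
    std::string nm = "up" + std::to_string(i + 1);
    out[nm + "_W"] = wrap(net.ups[i].W.g);
    out[nm + "_b"] = wrap(vec(net.ups[i].b.g.col(0)));
    out[nm + "_gamma"] = wrap(vec(net.ups[i].gamma.g.col(0)));
    out[nm + "_beta"] = wrap(vec(net.ups[i].beta.g.col(0)));
    push_grads(out, net.dec[2 * i], dec_name(i, 0));
    push_grads(out, net.dec[2 * i + 1], dec_name(i, 1));
  }
  out["final_W"] = wrap(net.fin.W.g);
  out["final_b"] = wrap(vec(net.fin.b.g.col(0)));
  out[".loss"] = loss;
  return out;
}

// [[Rcpp::export]]
double unet_loss_cpp(List params, IntegerVector widths, arma::cube X,
                     arma::cube Y, double dice_eps) {
  UNet net;
  list_to_net(params, net, widths_vec(widths));
  const int H = X.n_rows, W = X.n_cols, B = X.n_slices;
  mat X0(arma::vectorise(X).t());
  mat G0(arma::vectorise(Y).t());
  mat P = net.forward(X0, H, W, B, true);
  mat dP;
  return dice_loss_grad(P, G0, dice_eps, B, dP);
}

// [[Rcpp::export]]
List unet_train_cpp(List params, IntegerVector widths, arma::cube X,
                    arma::cube Y, double lr, int batch_size, int epochs,
                    int seed, double dice_eps) {
  UNet net;
  list_to_net(params, net, widths_vec(widths));
  const int H = X.n_rows, W = X.n_cols, N = X.n_slices;
  if ((int)Y.n_slices != N || (int)Y.n_rows != H || (int)Y.n_cols != W)
    stop("incompatible shapes: images and masks differ");
  if (N < 1) stop("nothing to train on");
  std::mt19937 rng((unsigned)seed);
  std::vector<int> order(N);
  for (int i = 0; i < N; ++i) order[i] = i;

  NumericVector history(epochs);
  double best_loss = arma::datum::inf;
  List best_params = net_to_list(net);
  int best_epoch = 0;
  long t = 0;
  const int HW = H * W;

  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(order.begin(), order.end(), rng);
    double ep_loss = 0;
    int n_batches = 0;
    for (int start = 0; start < N; start += batch_size) {
      const int B = std::min(batch_size, N - start);
      mat Xb(1, (arma::uword)HW * B), Gb(1, (arma::uword)HW * B);
      for (int k = 0; k < B; ++k) {
        const int idx = order[start + k];
        Xb.cols((arma::uword)k * HW, (arma::uword)(k + 1) * HW - 1) =
            arma::vectorise(X.slice(idx)).t();
        Gb.cols((arma::uword)k * HW, (arma::uword)(k + 1) * HW - 1) =
            arma::vectorise(Y.slice(idx)).t();
      }
      mat P = net.forward(Xb, H, W, B, true);
      mat dP;
      ep_loss += dice_loss_grad(P, Gb, dice_eps, B, dP);
      ++n_batches;
      net.backward(dP, H, W, B);
      net.adam_all(lr, ++t);
    }
    ep_loss /= n_batches;
    history[ep] = ep_loss;
    if (ep_loss < best_loss) {
      best_loss = ep_loss;
      best_params = net_to_list(net);
      best_epoch = ep + 1;
    }
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["params"] = best_params,
                      _["loss_history"] = history,
                      _["best_epoch"] = best_epoch,
                      _["best_loss"] = best_loss);
}
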