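// Dual-head U-Net: segmentation backbone (FSeg) with a bottleneck-attached
// patch-classification arm (FClass). Plain conv(3x3, same) + ReLU blocks,
// channel doubling per level, 2x2 max-pooling, nearest-neighbour upsampling
// with skip concatenation, and a downsampling module -> GAP -> fc stack for
// the classification arm. Forward, focal-loss and NT-Xent gradients, and
// full backpropagation are implemented here; optimisation lives in R.
//
// Layout conventions: images are arma::cube (rows x cols x channels);
// conv weights are (9*Cin) x Cout matrices with column index
// k = c*9 + (dy+1)*3 + (dx+1); fc weights are (in x out).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::cube;
using arma::mat;
using arma::vec;
using arma::uword;

static mat im2col3(const cube& X) {
  const uword H = X.n_rows, W = X.n_cols, C = X.n_slices;
  mat col(H * W, 9 * C, arma::fill::zeros);
  for (uword c = 0; c < C; ++c) {
    const mat& S = X.slice(c);
    for (int dy = -1; dy <= 1; ++dy) {
      for (int dx = -1; dx <= 1; ++dx) {
        const uword k = c * 9 + (dy + 1) * 3 + (dx + 1);
        // destination rows (r) and cols (w) with valid source r+dy, w+dx
        const uword r0 = (dy < 0) ? 1 : 0, r1 = (dy > 0) ? H - 1 : H;
        const uword c0 = (dx < 0) ? 1 : 0, c1 = (dx > 0) ? W - 1 : W;
        for (uword w = c0; w < c1; ++w) {
          const double* src = S.colptr(w + dx);
          double* dst = col.colptr(k) + w * H;
          for (uword r = r0; r < r1; ++r) dst[r] = src[r + dy];
        }
      }
    }
  }
  return col;
}

// scatter-add of a column matrix back to image gradient (adjoint of im2col3)
static cube col2im3(const mat& G, uword H, uword W, uword C) {
  cube dX(H, W, C, arma::fill::zeros);
  for (uword c = 0; c < C; ++c) {
    mat& S = dX.slice(c);
    for (int dy = -1; dy <= 1; ++dy) {
      for (int dx = -1; dx <= 1; ++dx) {
        const uword k = c * 9 + (dy + 1) * 3 + (dx + 1);
        const uword r0 = (dy < 0) ? 1 : 0, r1 = (dy > 0) ? H - 1 : H;
        const uword c0 = (dx < 0) ? 1 : 0, c1 = (dx > 0) ? W - 1 : W;
        for (uword w = c0; w < c1; ++w) {
          double* dst = S.colptr(w + dx);
          const double* src = G.colptr(k) + w * H;
          for (uword r = r0; r < r1; ++r) dst[r + dy] += src[r];
        }
      }
    }
  }
  return dX;
}

static cube conv3_fwd(const cube& X, const mat& Wt, const vec& b) {
  const uword H = X.n_rows, W = X.n_cols;
  mat out = im2col3(X) * Wt;          // (H*W) x Cout
  out.each_row() += b.t();
  cube Y(H, W, Wt.n_cols);
  for (uword o = 0; o < Wt.n_cols; ++o)
    Y.slice(o) = arma::reshape(out.col(o), H, W);
  return Y;
}

// backward through conv3: given dY, input X and weights; accumulates dW, db
static cube conv3_bwd(const cube& X, const mat& Wt, const cube& dY,
                      mat& dW, vec& db) {
  const uword H = X.n_rows, W = X.n_cols;
  mat dOut(H * W, dY.n_slices);
  for (uword o = 0; o < dY.n_slices; ++o)
    dOut.col(o) = arma::vectorise(dY.slice(o));
  mat col = im2col3(X);
  dW += col.t() * dOut;
  db += arma::sum(dOut, 0).t();
  mat dCol = dOut * Wt.t();
  return col2im3(dCol, H, W, X.n_slices);
}

static cube conv1_fwd(const cube& X, const mat& Wt, const vec& b) {
  const uword H = X.n_rows, W = X.n_cols, C = X.n_slices;
  mat xf(H * W, C);
  for (uword c = 0; c < C; ++c) xf.col(c) = arma::vectorise(X.slice(c));
  mat out = xf * Wt;
  out.each_row() += b.t();
  cube Y(H, W, Wt.n_cols);
  for (uword o = 0; o < Wt.n_cols; ++o)
    Y.slice(o) = arma::reshape(out.col(o), H, W);
  return Y;
}

static cube conv1_bwd(const cube& X, const mat& Wt, const cube& dY,
                      mat& dW, vec& db) {
  const uword H = X.n_rows, W = X.n_cols, C = X.n_slices;
  mat xf(H * W, C), dOut(H * W, dY.n_slices);
  for (uword c = 0; c < C; ++c) xf.col(c) = arma::vectorise(X.slice(c));
  for (uword o = 0; o < dY.n_slices; ++o)
    dOut.col(o) = arma::vectorise(dY.slice(o));
  dW += xf.t() * dOut;
  db += arma::sum(dOut, 0).t();
  mat dXf = dOut * Wt.t();
  cube dX(H, W, C);
  for (uword c = 0; c < C; ++c) dX.slice(c) = arma::reshape(dXf.col(c), H, W);
  return dX;
}

static void relu_(cube& X) { X.transform([](double v) { return v > 0 ? v : 0.0; }); }

static cube relu_bwd(const cube& act, const cube& dY) {
  cube dX = dY;
  for (uword i = 0; i < act.n_elem; ++i) if (act(i) <= 0) dX(i) = 0;
  return dX;
}

static cube maxpool_fwd(const cube& X, arma::ucube& idx) {
  const uword H = X.n_rows / 2, W = X.n_cols / 2, C = X.n_slices;
  cube Y(H, W, C);
  idx.set_size(H, W, C);
  for (uword c = 0; c < C; ++c) {
    for (uword w = 0; w < W; ++w) {
      for (uword r = 0; r < H; ++r) {
        double best = -1e300; uword bi = 0;
        for (uword dr = 0; dr < 2; ++dr)
          for (uword dc = 0; dc < 2; ++dc) {
            double v = X(2 * r + dr, 2 * w + dc, c);
            if (v > best) { best = v; bi = (2 * w + dc) * X.n_rows + 2 * r + dr; }
          }
        Y(r, w, c) = best;
        idx(r, w, c) = bi;
      }
    }
  }
  return Y;
}

static cube maxpool_bwd(const arma::ucube& idx, const cube& dY,
                        uword H, uword W) {
  cube dX(H, W, dY.n_slices, arma::fill::zeros);
  for (uword c = 0; c < dY.n_slices; ++c) {
    for (uword w = 0; w < dY.n_cols; ++w)
      for (uword r = 0; r < dY.n_rows; ++r)
        dX.slice(c)(idx(r, w, c)) += dY(r, w, c);
  }
  return dX;
}

static cube upsample_fwd(const cube& X) {
  const uword H = X.n_rows, W = X.n_cols, C = X.n_slices;
  cube Y(2 * H, 2 * W, C);
  for (uword c = 0; c < C; ++c)
    for (uword w = 0; w < W; ++w)
      for (uword r = 0; r < H; ++r) {
        double v = X(r, w, c);
        Y(2 * r, 2 * w, c) = v; Y(2 * r + 1, 2 * w, c) = v;
        Y(2 * r, 2 * w + 1, c) = v; Y(2 * r + 1, 2 * w + 1, c) = v;
      }
  return Y;
}

static cube upsample_bwd(const cube& dY) {
  const uword H = dY.n_rows / 2, W = dY.n_cols / 2, C = dY.n_slices;
  cube dX(H, W, C);
  for (uword c = 0; c < C; ++c)
    for (uword w = 0; w < W; ++w)
      for (uword r = 0; r < H; ++r)
        dX(r, w, c) = dY(2 * r, 2 * w, c) + dY(2 * r + 1, 2 * w, c) +
                      dY(2 * r, 2 * w + 1, c) + dY(2 * r + 1, 2 * w + 1, c);
  return dX;
}

static cube concat(const cube& A, const cube& B) {
  cube Y(A.n_rows, A.n_cols, A.n_slices + B.n_slices);
  Y.slices(0, A.n_slices - 1) = A;
  Y.slices(A.n_slices, A.n_slices + B.n_slices - 1) = B;
  return Y;
}

struct NetCfg {
  int depth, base_width, fc1, fc2, in_ch;
};

static NetCfg read_cfg(const List& cfg) {
  NetCfg c;
  c.depth = as<int>(cfg["depth"]);
  c.base_width = as<int>(cfg["base_width"]);
  c.fc1 = as<int>(cfg["fc1"]);
  c.fc2 = as<int>(cfg["fc2"]);
  c.in_ch = as<int>(cfg["in_ch"]);
  return c;
}

static int chan_at(const NetCfg& c, int level) {
  return c.base_width << (level - 1);
}

static mat getW(const List& p, const std::string& nm) {
  return as<mat>(p[nm]);
}
static vec getb(const List& p, const std::string& nm) {
  return as<vec>(p[nm]);
}

// Full per-sample forward pass with caches kept for backprop.
struct FwdCache {
  std::vector<cube> enc_a, enc_b;      // post-ReLU activations per level
  std::vector<cube> pool_in;           // (unused sizes only) kept implicitly
  std::vector<arma::ucube> pool_idx;
  std::vector<uword> pool_H, pool_W;
  cube input;
  std::vector<cube> dec_up, dec_upconv, dec_cat, dec_a, dec_b;
  cube seg_logits;
  // cls arm
  std::vector<arma::ucube> cls_pool_idx;
  std::vector<uword> cls_H, cls_W;
  std::vector<cube> cls_pool_out, cls_a, cls_b;
  vec gap, h1, h2, cls_logits;
  bool has_cls = false;
};

static void forward_one(const cube& X, const List& par, const NetCfg& cfg,
                        bool with_cls, FwdCache& cc) {
  const int D = cfg.depth;
  if (X.n_rows % (1u << (D - 1)) || X.n_cols % (1u << (D - 1)))
    stop("input spatial size must be divisible by 2^(depth-1)");
  cc.input = X;
  cube x = X;
  cc.enc_a.resize(D); cc.enc_b.resize(D);
  cc.pool_idx.resize(D - 1); cc.pool_H.resize(D - 1); cc.pool_W.resize(D - 1);
  char nm[64];
  for (int l = 1; l <= D; ++l) {
    snprintf(nm, 64, "enc%d_Wa", l);
    cube a = conv3_fwd(x, getW(par, nm), getb(par, std::string("enc") + std::to_string(l) + "_ba"));
    relu_(a); cc.enc_a[l - 1] = a;
    snprintf(nm, 64, "enc%d_Wb", l);
    cube b = conv3_fwd(a, getW(par, nm), getb(par, std::string("enc") + std::to_string(l) + "_bb"));
    relu_(b); cc.enc_b[l - 1] = b;
    if (l < D) {
      cc.pool_H[l - 1] = b.n_rows; cc.pool_W[l - 1] = b.n_cols;
      x = maxpool_fwd(b, cc.pool_idx[l - 1]);
    }
  }
  // decoder
  cube y = cc.enc_b[D - 1];
  cc.dec_up.resize(D - 1); cc.dec_upconv.resize(D - 1);
  cc.dec_cat.resize(D - 1); cc.dec_a.resize(D - 1); cc.dec_b.resize(D - 1);
  for (int l = D - 1; l >= 1; --l) {
    const int i = l - 1;
    cube up = upsample_fwd(y);
    cc.dec_up[i] = up;
    snprintf(nm, 64, "dec%d_Wu", l);
    cube uc = conv3_fwd(up, getW(par, nm), getb(par, std::string("dec") + std::to_string(l) + "_bu"));
    relu_(uc); cc.dec_upconv[i] = uc;
    cube cat = concat(uc, cc.enc_b[i]);
    cc.dec_cat[i] = cat;
    snprintf(nm, 64, "dec%d_Wa", l);
    cube a = conv3_fwd(cat, getW(par, nm), getb(par, std::string("dec") + std::to_string(l) + "_ba"));
    relu_(a); cc.dec_a[i] = a;
    snprintf(nm, 64, "dec%d_Wb", l);
    cube b = conv3_fwd(a, getW(par, nm), getb(par, std::string("dec") + std::to_string(l) + "_bb"));
    relu_(b); cc.dec_b[i] = b;
    y = b;
  }
  cc.seg_logits = conv1_fwd(y, getW(par, "out_W"), getb(par, "out_b"));

  if (with_cls) {
    cube z = cc.enc_b[D - 1];
    if (z.n_rows % 4 || z.n_cols % 4)
      stop("bottleneck size must be divisible by 4 for the classification arm");
    cc.cls_pool_idx.resize(2); cc.cls_H.resize(2); cc.cls_W.resize(2);
    cc.cls_pool_out.resize(2); cc.cls_a.resize(2); cc.cls_b.resize(2);
    for (int m = 1; m <= 2; ++m) {
      const int i = m - 1;
      cc.cls_H[i] = z.n_rows; cc.cls_W[i] = z.n_cols;
      cube p = maxpool_fwd(z, cc.cls_pool_idx[i]);
      cc.cls_pool_out[i] = p;
      snprintf(nm, 64, "cls%d_Wa", m);
      cube a = conv3_fwd(p, getW(par, nm), getb(par, std::string("cls") + std::to_string(m) + "_ba"));
      relu_(a); cc.cls_a[i] = a;
      snprintf(nm, 64, "cls%d_Wb", m);
      cube b = conv3_fwd(a, getW(par, nm), getb(par, std::string("cls") + std::to_string(m) + "_bb"));
      relu_(b); cc.cls_b[i] = b;
      z = b;
    }
    const uword C = z.n_slices;
    cc.gap.set_size(C);
    for (uword c = 0; c < C; ++c) cc.gap(c) = arma::accu(z.slice(c)) / (z.n_rows * z.n_cols);
    vec h1 = getW(par, "fc1_W").t() * cc.gap + getb(par, "fc1_b");
    h1.transform([](double v) { return v > 0 ? v : 0.0; });
    cc.h1 = h1;
    vec h2 = getW(par, "fc2_W").t() * h1 + getb(par, "fc2_b");
    h2.transform([](double v) { return v > 0 ? v : 0.0; });
    cc.h2 = h2;
    cc.cls_logits = getW(par, "fc3_W").t() * h2 + getb(par, "fc3_b");
    cc.has_cls = true;
  }
}

// Backward pass; dSeg is gradient wrt seg logits, dEmb wrt the 256-d
// embedding, dClsLogit wrt the 2-node output. Accumulates into `grads`
// (a pre-built named list of zero-filled arrays handled R-side via XPtr-free
// approach: we accumulate into std::map then return).
struct GradAcc {
  std::map<std::string, mat> W;
  std::map<std::string, vec> b;
  void addW(const std::string& n, const mat& g) {
    auto it = W.find(n);
    if (it == W.end()) W[n] = g; else it->second += g;
  }
  void addb(const std::string& n, const vec& g) {
    auto it = b.find(n);
    if (it == b.end()) b[n] = g; else it->second += g;
  }
};

static void backward_one(const FwdCache& cc, const List& par, const NetCfg& cfg,
                         const cube& dSeg, const vec& dEmb, const vec& dClsLogit,
                         GradAcc& g) {
  const int D = cfg.depth;
  char nm[64];
  // ---- classification arm
  cube dBottle_cls;
  bool have_cls_grad = cc.has_cls &&
    (arma::norm(dEmb, 2) > 0 || arma::norm(dClsLogit, 2) > 0);
  if (have_cls_grad) {
    mat fc3_W = getW(par, "fc3_W");
    vec dh2 = dEmb + fc3_W * dClsLogit;
    g.addW("fc3_W", cc.h2 * dClsLogit.t());
    g.addb("fc3_b", dClsLogit);
    for (uword i = 0; i < dh2.n_elem; ++i) if (cc.h2(i) <= 0) dh2(i) = 0;
    mat fc2_W = getW(par, "fc2_W");
    g.addW("fc2_W", cc.h1 * dh2.t());
    g.addb("fc2_b", dh2);
    vec dh1 = fc2_W * dh2;
    for (uword i = 0; i < dh1.n_elem; ++i) if (cc.h1(i) <= 0) dh1(i) = 0;
    mat fc1_W = getW(par, "fc1_W");
    g.addW("fc1_W", cc.gap * dh1.t());
    g.addb("fc1_b", dh1);
    vec dgap = fc1_W * dh1;
    const cube& zlast = cc.cls_b[1];
    cube dz(zlast.n_rows, zlast.n_cols, zlast.n_slices);
    const double inv = 1.0 / (zlast.n_rows * zlast.n_cols);
    for (uword c = 0; c < zlast.n_slices; ++c) dz.slice(c).fill(dgap(c) * inv);
    for (int m = 2; m >= 1; --m) {
      const int i = m - 1;
      dz = relu_bwd(cc.cls_b[i], dz);
      snprintf(nm, 64, "cls%d_Wb", m);
      mat dW(getW(par, nm).n_rows, getW(par, nm).n_cols, arma::fill::zeros);
      vec db(getW(par, nm).n_cols, arma::fill::zeros);
      cube da = conv3_bwd(cc.cls_a[i], getW(par, nm), dz, dW, db);
      g.addW(nm, dW); g.addb(std::string("cls") + std::to_string(m) + "_bb", db);
      da = relu_bwd(cc.cls_a[i], da);
      snprintf(nm, 64, "cls%d_Wa", m);
      mat dW2(getW(par, nm).n_rows, getW(par, nm).n_cols, arma::fill::zeros);
      vec db2(getW(par, nm).n_cols, arma::fill::zeros);
      cube dp = conv3_bwd(cc.cls_pool_out[i], getW(par, nm), da, dW2, db2);
      g.addW(nm, dW2); g.addb(std::string("cls") + std::to_string(m) + "_ba", db2);
      dz = maxpool_bwd(cc.cls_pool_idx[i], dp, cc.cls_H[i], cc.cls_W[i]);
    }
    dBottle_cls = dz;
  }

  // ---- segmentation head
  bool have_seg_grad = arma::accu(arma::abs(dSeg)) > 0;
  std::vector<cube> dskip(D);  // gradient wrt enc_b activations
  cube dy;
  if (have_seg_grad) {
    {
      mat dW(getW(par, "out_W").n_rows, getW(par, "out_W").n_cols, arma::fill::zeros);
      vec db(2, arma::fill::zeros);
      dy = conv1_bwd(cc.dec_b[0], getW(par, "out_W"), dSeg, dW, db);
      g.addW("out_W", dW); g.addb("out_b", db);
    }
    for (int l = 1; l <= D - 1; ++l) {
      const int i = l - 1;
      dy = relu_bwd(cc.dec_b[i], dy);
      snprintf(nm, 64, "dec%d_Wb", l);
      mat dWb(getW(par, nm).n_rows, getW(par, nm).n_cols, arma::fill::zeros);
      vec dbb(getW(par, nm).n_cols, arma::fill::zeros);
      cube da = conv3_bwd(cc.dec_a[i], getW(par, nm), dy, dWb, dbb);
      g.addW(nm, dWb); g.addb(std::string("dec") + std::to_string(l) + "_bb", dbb);
      da = relu_bwd(cc.dec_a[i], da);
      snprintf(nm, 64, "dec%d_Wa", l);
      mat dWa(getW(par, nm).n_rows, getW(par, nm).n_cols, arma::fill::zeros);
      vec dba(getW(par, nm).n_cols, arma::fill::zeros);
      cube dcat = conv3_bwd(cc.dec_cat[i], getW(par, nm), da, dWa, dba);
      g.addW(nm, dWa); g.addb(std::string("dec") + std::to_string(l) + "_ba", dba);
      const uword cu = cc.dec_upconv[i].n_slices;
      cube duc = dcat.slices(0, cu - 1);
      dskip[i] = dcat.slices(cu, dcat.n_slices - 1);
      duc = relu_bwd(cc.dec_upconv[i], duc);
      snprintf(nm, 64, "dec%d_Wu", l);
      mat dWu(getW(par, nm).n_rows, getW(par, nm).n_cols, arma::fill::zeros);
      vec dbu(getW(par, nm).n_cols, arma::fill::zeros);
      cube dup = conv3_bwd(cc.dec_up[i], getW(par, nm), duc, dWu, dbu);
      g.addW(nm, dWu); g.addb(std::string("dec") + std::to_string(l) + "_bu", dbu);
      dy = upsample_bwd(dup);
    }
  }

  // ---- encoder (combine decoder skip grads, bottleneck grads from both heads)
  cube dnext;  // gradient flowing into the pooled output of level l
  for (int l = D; l >= 1; --l) {
    const int i = l - 1;
    cube db_grad;
    bool any = false;
    if (l == D) {
      if (have_seg_grad) { db_grad = dy; any = true; }
      if (have_cls_grad) {
        if (any) db_grad += dBottle_cls; else { db_grad = dBottle_cls; any = true; }
      }
    } else {
      if (dnext.n_elem > 0) {
        db_grad = maxpool_bwd(cc.pool_idx[i], dnext, cc.pool_H[i], cc.pool_W[i]);
        any = true;
      }
      if (have_seg_grad && dskip[i].n_elem > 0) {
        if (any) db_grad += dskip[i]; else { db_grad = dskip[i]; any = true; }
      }
    }
    if (!any) { dnext.reset(); continue; }
    db_grad = relu_bwd(cc.enc_b[i], db_grad);
    snprintf(nm, 64, "enc%d_Wb", l);
    mat dWb(getW(par, nm).n_rows, getW(par, nm).n_cols, arma::fill::zeros);
    vec dbb(getW(par, nm).n_cols, arma::fill::zeros);
    cube da = conv3_bwd(cc.enc_a[i], getW(par, nm), db_grad, dWb, dbb);
    g.addW(nm, dWb); g.addb(std::string("enc") + std::to_string(l) + "_bb", dbb);
    da = relu_bwd(cc.enc_a[i], da);
    snprintf(nm, 64, "enc%d_Wa", l);
    mat dWa(getW(par, nm).n_rows, getW(par, nm).n_cols, arma::fill::zeros);
    vec dba(getW(par, nm).n_cols, arma::fill::zeros);
    cube src;
    if (l == 1) src = cc.input;
    else {
      // input of level l is maxpool of enc_b[l-2]; recompute it
      arma::ucube tmp_idx;
      src = maxpool_fwd(cc.enc_b[l - 2], tmp_idx);
    }
    cube dx = conv3_bwd(src, getW(par, nm), da, dWa, dba);
    g.addW(nm, dWa); g.addb(std::string("enc") + std::to_string(l) + "_ba", dba);
    if (l > 1) dnext = dx; else dnext.reset();
  }
}

// focal loss and gradient wrt 2-class seg logits (slice 0 = background,
// slice 1 = fiber). Returns loss (pixel mean); writes dSeg (scaled by the
// caller-provided weight / denominator).
static double focal_forward_backward(const cube& logits, const mat& y,
                                     double alpha, double gamma,
                                     double scale, cube& dSeg) {
  const uword H = logits.n_rows, W = logits.n_cols;
  double loss = 0;
  dSeg.set_size(H, W, 2);
  const double eps = 1e-7;
  for (uword w = 0; w < W; ++w) {
    for (uword r = 0; r < H; ++r) {
      const double d = logits(r, w, 1) - logits(r, w, 0);
      double p = 1.0 / (1.0 + std::exp(-d));
      p = std::min(std::max(p, eps), 1.0 - eps);
      const double t = y(r, w);
      const double pt = t > 0.5 ? p : 1.0 - p;
      const double at = t > 0.5 ? alpha : 1.0 - alpha;
      loss += -at * std::pow(1.0 - pt, gamma) * std::log(pt);
      // dL/dpt
      double dpt = -at * (std::pow(1.0 - pt, gamma) / pt -
                          (gamma > 0 ? gamma * std::pow(1.0 - pt, gamma - 1.0) * std::log(pt) : 0.0));
      double dp = (t > 0.5) ? dpt : -dpt;
      const double dd = dp * p * (1.0 - p);
      dSeg(r, w, 1) = dd * scale;
      dSeg(r, w, 0) = -dd * scale;
    }
  }
  return loss / (H * W);
}

// NT-Xent loss and gradient for 2N x Dm embeddings arranged as consecutive
// positive pairs. Returns loss; fills dF (2N x Dm).
static double ntxent_forward_backward(const mat& F, double tau, mat& dF) {
  const uword n2 = F.n_rows;
  vec nrm(n2);
  for (uword i = 0; i < n2; ++i) nrm(i) = std::max(arma::norm(F.row(i), 2), 1e-12);
  mat Z = F;
  Z.each_col() /= nrm;
  mat S = Z * Z.t() / tau;
  mat P(n2, n2, arma::fill::zeros);  // row-softmax over k != i
  double loss = 0;
  for (uword i = 0; i < n2; ++i) {
    const uword j = (i % 2 == 0) ? i + 1 : i - 1;
    double m = -1e300;
    for (uword k = 0; k < n2; ++k) if (k != i) m = std::max(m, S(i, k));
    double den = 0;
    for (uword k = 0; k < n2; ++k) if (k != i) den += std::exp(S(i, k) - m);
    loss += (m + std::log(den)) - S(i, j);
    for (uword k = 0; k < n2; ++k)
      if (k != i) P(i, k) = std::exp(S(i, k) - m) / den;
  }
  loss /= n2;
  // dL/dS(i,k) = (P(i,k) - [k == partner(i)]) / n2 ; S(i,k) and S(k,i) are
  // the same dot product, so combine both contributions on dZ.
  mat G(n2, n2, arma::fill::zeros);
  for (uword i = 0; i < n2; ++i) {
    const uword j = (i % 2 == 0) ? i + 1 : i - 1;
    for (uword k = 0; k < n2; ++k) {
      if (k == i) continue;
      G(i, k) += (P(i, k) - (k == j ? 1.0 : 0.0)) / n2;
    }
  }
  mat dZ = (G + G.t()) * Z / tau;
  dF.set_size(n2, F.n_cols);
  for (uword i = 0; i < n2; ++i) {
    arma::rowvec zi = Z.row(i);
    arma::rowvec gi = dZ.row(i);
    dF.row(i) = (gi - arma::dot(gi, zi) * zi) / nrm(i);
  }
  return loss;
}

// [[Rcpp::export(name = ".nn_forward_cpp")]]
List nn_forward_cpp(const arma::cube& image, const List& params,
                    const List& cfg, bool with_cls) {
  NetCfg c = read_cfg(cfg);
  FwdCache cc;
  forward_one(image, params, c, with_cls, cc);
  const uword H = cc.seg_logits.n_rows, W = cc.seg_logits.n_cols;
  mat prob(H, W);
  for (uword w = 0; w < W; ++w)
    for (uword r = 0; r < H; ++r) {
      const double d = cc.seg_logits(r, w, 1) - cc.seg_logits(r, w, 0);
      prob(r, w) = 1.0 / (1.0 + std::exp(-d));
    }
  List out = List::create(
    _["seg_prob"] = prob,
    _["seg_logits"] = cc.seg_logits);
  if (with_cls) {
    out["cls_logits"] = NumericVector(cc.cls_logits.begin(), cc.cls_logits.end());
    out["embedding"] = NumericVector(cc.h2.begin(), cc.h2.end());
  }
  return out;
}

// [[Rcpp::export(name = ".nn_train_step_cpp")]]
List nn_train_step_cpp(const List& images, const List& labels,
                       const List& params, const List& cfg,
                       const IntegerVector& contrastive_order,
                       double alpha, double gamma, double tau,
                       double w_focal, double w_con,
                       const std::string& con_features) {
  NetCfg c = read_cfg(cfg);
  const int N = images.size();
  if (labels.size() != N) stop("images and labels must have equal length");
  const bool use_con = contrastive_order.size() >= 4 && w_con > 0;
  std::vector<FwdCache> caches(N);
  for (int i = 0; i < N; ++i) {
    cube X = as<cube>(images[i]);
    forward_one(X, params, c, use_con, caches[i]);
  }
  // focal loss over labelled samples
  int n_lab = 0;
  for (int i = 0; i < N; ++i) if (!Rf_isNull(labels[i])) ++n_lab;
  double focal_total = 0;
  std::vector<cube> dSeg(N);
  for (int i = 0; i < N; ++i) {
    if (Rf_isNull(labels[i])) {
      dSeg[i].set_size(caches[i].seg_logits.n_rows, caches[i].seg_logits.n_cols, 2);
      dSeg[i].zeros();
      continue;
    }
    mat y = as<mat>(labels[i]);
    const double scale = w_focal / (n_lab * y.n_elem);
    focal_total += focal_forward_backward(caches[i].seg_logits, y, alpha, gamma,
                                          scale, dSeg[i]);
  }
  const double focal_loss_val = n_lab > 0 ? focal_total / n_lab : 0.0;

  // contrastive loss over the ordered subset
  double con_loss_val = 0;
  std::vector<vec> dEmb(N), dCls(N);
  const int emb_dim = use_con ? (con_features == "logits" ? 2 : c.fc2) : 0;
  for (int i = 0; i < N; ++i) {
    dEmb[i] = vec(c.fc2, arma::fill::zeros);
    dCls[i] = vec(2, arma::fill::zeros);
  }
  if (use_con) {
    const int M = contrastive_order.size();
    mat F(M, emb_dim);
    for (int m = 0; m < M; ++m) {
      const int i = contrastive_order[m];  // 0-based
      F.row(m) = (con_features == "logits")
        ? caches[i].cls_logits.t()
        : caches[i].h2.t();
    }
    mat dF;
    con_loss_val = ntxent_forward_backward(F, tau, dF);
    for (int m = 0; m < M; ++m) {
      const int i = contrastive_order[m];
      if (con_features == "logits") dCls[i] += w_con * dF.row(m).t();
      else dEmb[i] += w_con * dF.row(m).t();
    }
  }

  GradAcc g;
  for (int i = 0; i < N; ++i) {
    backward_one(caches[i], params, c, dSeg[i], dEmb[i], dCls[i], g);
  }
  List grads;
  for (auto& kv : g.W) grads[kv.first] = kv.second;
  for (auto& kv : g.b) grads[kv.first] = NumericVector(kv.second.begin(), kv.second.end());

  List probs(N);
  for (int i = 0; i < N; ++i) {
    const cube& sl = caches[i].seg_logits;
    mat p(sl.n_rows, sl.n_cols);
    for (uword w = 0; w < sl.n_cols; ++w)
      for (uword r = 0; r < sl.n_rows; ++r)
        p(r, w) = 1.0 / (1.0 + std::exp(-(sl(r, w, 1) - sl(r, w, 0))));
    probs[i] = p;
  }
  return List::create(
    _["grads"] = grads,
    _["focal_loss"] = focal_loss_val,
    _["con_loss"] = con_loss_val,
    _["loss"] = w_focal * focal_loss_val + w_con * con_loss_val,
    _["seg_probs"] = probs);
}

// [[Rcpp::export(name = ".ntxent_cpp")]]
List ntxent_cpp(const arma::mat& features, double tau) {
  mat dF;
  double loss = ntxent_forward_backward(features, tau, dF);
  return List::create(_["loss"] = loss, _["grad"] = dF);
}
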