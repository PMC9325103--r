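// 2D U-net: encoder-decoder with 4 max-pool / 4 up-conv stages, skip
// connections by concatenation, per-pixel softmax over 9 classes.
// Implemented directly on BLAS: 3x3 same-convolutions as im2col + GEMM in
// single precision, manual reverse-mode gradients, Adam updates.
//
// Layout: feature maps are arma::fmat of shape (channels, H*W) with pixel
// index r + c*H (column-major, matching R matrices).

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <random>
using namespace arma;

struct Param {
  fmat W, dW, mW, vW;
  fvec b, db, mb, vb;
  void init_shapes(int rows, int cols) {
    W.set_size(rows, cols); dW.zeros(rows, cols);
    mW.zeros(rows, cols);  vW.zeros(rows, cols);
    b.zeros(rows); db.zeros(rows); mb.zeros(rows); vb.zeros(rows);
  }
};

// truncated (at 2 sd) Glorot normal
static void glorot_fill(fmat& W, double fan_in, double fan_out, std::mt19937& rng) {
  double sd = std::sqrt(2.0 / (fan_in + fan_out));
  std::normal_distribution<double> nd(0.0, sd);
  for (uword i = 0; i < W.n_elem; ++i) {
    double x;
    do { x = nd(rng); } while (std::abs(x) > 2.0 * sd);
    W[i] = (float)x;
  }
}

// ---- im2col for 3x3 same-padding convolutions ----------------------------
static void im2col3(const fmat& X, int H, int W, fmat& K) {
  int Cin = X.n_rows;
  K.zeros(Cin * 9, H * W);
  int o = 0;
  for (int dc = -1; dc <= 1; ++dc) {
    for (int dr = -1; dr <= 1; ++dr, ++o) {
      for (int c = 0; c < W; ++c) {
        int cc = c + dc;
        if (cc < 0 || cc >= W) continue;
        int rlo = std::max(0, -dr), rhi = std::min(H, H - dr);
        if (rhi <= rlo) continue;
        K.submat(o * Cin, c * H + rlo, (o + 1) * Cin - 1, c * H + rhi - 1) =
          X.cols(cc * H + rlo + dr, cc * H + rhi - 1 + dr);
      }
    }
  }
}

// adjoint of im2col3: scatter-add column blocks back into dX
static void col2im3(const fmat& dK, int H, int W, fmat& dX) {
  int Cin = dX.n_rows;
  int o = 0;
  for (int dc = -1; dc <= 1; ++dc) {
    for (int dr = -1; dr <= 1; ++dr, ++o) {
      for (int c = 0; c < W; ++c) {
        int cc = c + dc;
        if (cc < 0 || cc >= W) continue;
        int rlo = std::max(0, -dr), rhi = std::min(H, H - dr);
        if (rhi <= rlo) continue;
        dX.cols(cc * H + rlo + dr, cc * H + rhi - 1 + dr) +=
          dK.submat(o * Cin, c * H + rlo, (o + 1) * Cin - 1, c * H + rhi - 1);
      }
    }
  }
}

// conv3x3 + ReLU forward: A = relu(W * im2col(X) + b)
static fmat conv_relu(const Param& p, const fmat& X, int H, int W, fmat& Kbuf) {
  im2col3(X, H, W, Kbuf);
  fmat A = p.W * Kbuf;
  A.each_col() += p.b;
  return clamp(A, 0.0f, std::numeric_limits<float>::max());
}

// backward through ReLU(conv): consumes dA, uses stored activation A for the
// ReLU mask and input X (recomputing im2col); returns dX, accumulates grads
static fmat conv_relu_backward(Param& p, const fmat& dA, const fmat& A,
                               const fmat& X, int H, int W, fmat& Kbuf) {
  fmat dZ = dA % conv_to<fmat>::from(A > 0.0f);
  p.db += sum(dZ, 1);
  im2col3(X, H, W, Kbuf);
  p.dW += dZ * Kbuf.t();
  fmat dK = p.W.t() * dZ;
  fmat dX(X.n_rows, X.n_cols, fill::zeros);
  col2im3(dK, H, W, dX);
  return dX;
}

// ---- 2x2 max pooling ------------------------------------------------------
static fmat maxpool(const fmat& X, int H, int W, umat& idx) {
  int C = X.n_rows, H2 = H / 2, W2 = W / 2;
  fmat Y(C, H2 * W2);
  idx.set_size(C, H2 * W2);
  for (int c2 = 0; c2 < W2; ++c2) {
    for (int r2 = 0; r2 < H2; ++r2) {
      int j = r2 + c2 * H2;
      int cand[4] = {2 * r2 + 2 * c2 * H, 2 * r2 + 1 + 2 * c2 * H,
                     2 * r2 + (2 * c2 + 1) * H, 2 * r2 + 1 + (2 * c2 + 1) * H};
      for (int ch = 0; ch < C; ++ch) {
        float best = X(ch, cand[0]); int bi = cand[0];
        for (int q = 1; q < 4; ++q)
          if (X(ch, cand[q]) > best) { best = X(ch, cand[q]); bi = cand[q]; }
        Y(ch, j) = best; idx(ch, j) = bi;
      }
    }
  }
  return Y;
}

static fmat maxpool_backward(const fmat& dY, const umat& idx, int n_in_cols) {
  fmat dX(dY.n_rows, n_in_cols, fill::zeros);
  for (uword j = 0; j < dY.n_cols; ++j)
    for (uword ch = 0; ch < dY.n_rows; ++ch)
      dX(ch, idx(ch, j)) += dY(ch, j);
  return dX;
}

// ---- 2x2 stride-2 transposed convolution (up-conv) ------------------------
// W layout: (Cout, Cin*4), offset o = dr + 2*dc, block cols [o*Cin, ...)
static fmat upconv(const Param& p, const fmat& X, int H, int W) {
  int Cin = X.n_rows, Cout = p.W.n_rows;
  int H2 = 2 * H, W2 = 2 * W;
  fmat Y(Cout, H2 * W2, fill::zeros);
  for (int o = 0; o < 4; ++o) {
    int dr = o % 2, dc = o / 2;
    fmat Yo = p.W.cols(o * Cin, (o + 1) * Cin - 1) * X;  // (Cout, H*W)
    for (int c = 0; c < W; ++c)
      for (int r = 0; r < H; ++r)
        Y.col((2 * r + dr) + (2 * c + dc) * H2) = Yo.col(r + c * H);
  }
  Y.each_col() += p.b;
  return Y;
}

static fmat upconv_backward(Param& p, const fmat& dY, const fmat& X, int H, int W) {
  int Cin = X.n_rows;
  int H2 = 2 * H;
  p.db += sum(dY, 1);
  fmat dX(Cin, H * W, fill::zeros);
  fmat dYo(dY.n_rows, H * W);
  for (int o = 0; o < 4; ++o) {
    int dr = o % 2, dc = o / 2;
    for (int c = 0; c < W; ++c)
      for (int r = 0; r < H; ++r)
        dYo.col(r + c * H) = dY.col((2 * r + dr) + (2 * c + dc) * H2);
    p.dW.cols(o * Cin, (o + 1) * Cin - 1) += dYo * X.t();
    dX += p.W.cols(o * Cin, (o + 1) * Cin - 1).t() * dYo;
  }
  return dX;
}

// ---- model ----------------------------------------------------------------
struct SampleCache {
  fmat x;
  fmat e1a, e1b, p1, e2a, e2b, p2, e3a, e3b, p3, e4a, e4b, e4d, p4;
  umat i1, i2, i3, i4;
  fmat bna, bnb, bnd;
  fmat u4, d4a, d4b, u3, d3a, d3b, u2, d2a, d2b, u1, d1a, d1b;
  fmat probs;
  fmat m4, mbn;   // dropout masks (already scaled by 1/keep)
  int H;
};

struct UNet {
  int f, n_class;
  // encoder convs e1a..e4b, bottleneck bna/bnb, decoder convs d4a..d1b
  Param e1a, e1b, e2a, e2b, e3a, e3b, e4a, e4b, bna, bnb;
  Param u4, u3, u2, u1;                   // up-convs
  Param d4a, d4b, d3a, d3b, d2a, d2b, d1a, d1b;
  Param fin;                               // 1x1 conv f -> n_class
  long t_adam = 0;
  std::mt19937 rng;
  std::vector<SampleCache> cache;
  fmat Kbuf;                               // scratch for im2col

  std::vector<Param*> params() {
    return {&e1a, &e1b, &e2a, &e2b, &e3a, &e3b, &e4a, &e4b, &bna, &bnb,
            &u4, &u3, &u2, &u1, &d4a, &d4b, &d3a, &d3b, &d2a, &d2b,
            &d1a, &d1b, &fin};
  }
};

static void init_conv(Param& p, int cin, int cout, std::mt19937& rng) {
  p.init_shapes(cout, cin * 9);
  glorot_fill(p.W, cin * 9.0, cout * 9.0, rng);
}
static void init_upconv(Param& p, int cin, int cout, std::mt19937& rng) {
  p.init_shapes(cout, cin * 4);
  glorot_fill(p.W, cin * 4.0, cout * 4.0, rng);
}

// [[Rcpp::export]]
SEXP unet_create(int base_filters, int n_class, int seed) {
  UNet* net = new UNet();
  net->f = base_filters; net->n_class = n_class;
  net->rng.seed((unsigned)seed);
  int f = base_filters;
  init_conv(net->e1a, 1, f, net->rng);      init_conv(net->e1b, f, f, net->rng);
  init_conv(net->e2a, f, 2 * f, net->rng);  init_conv(net->e2b, 2 * f, 2 * f, net->rng);
  init_conv(net->e3a, 2 * f, 4 * f, net->rng); init_conv(net->e3b, 4 * f, 4 * f, net->rng);
  init_conv(net->e4a, 4 * f, 8 * f, net->rng); init_conv(net->e4b, 8 * f, 8 * f, net->rng);
  init_conv(net->bna, 8 * f, 16 * f, net->rng); init_conv(net->bnb, 16 * f, 16 * f, net->rng);
  init_upconv(net->u4, 16 * f, 8 * f, net->rng);
  init_conv(net->d4a, 16 * f, 8 * f, net->rng); init_conv(net->d4b, 8 * f, 8 * f, net->rng);
  init_upconv(net->u3, 8 * f, 4 * f, net->rng);
  init_conv(net->d3a, 8 * f, 4 * f, net->rng); init_conv(net->d3b, 4 * f, 4 * f, net->rng);
  init_upconv(net->u2, 4 * f, 2 * f, net->rng);
  init_conv(net->d2a, 4 * f, 2 * f, net->rng); init_conv(net->d2b, 2 * f, 2 * f, net->rng);
  init_upconv(net->u1, 2 * f, f, net->rng);
  init_conv(net->d1a, 2 * f, f, net->rng); init_conv(net->d1b, f, f, net->rng);
  net->fin.init_shapes(n_class, f);
  glorot_fill(net->fin.W, f, n_class, net->rng);
  Rcpp::XPtr<UNet> ptr(net, true);
  return ptr;
}

static fmat dropout_mask(UNet& net, int rows, int cols, double keep) {
  std::uniform_real_distribution<double> ud(0.0, 1.0);
  fmat m(rows, cols);
  float inv = (float)(1.0 / keep);
  for (uword i = 0; i < m.n_elem; ++i) m[i] = ud(net.rng) < keep ? inv : 0.0f;
  return m;
}

// forward one sample; fills cache if train
static fmat forward_one(UNet& net, const fvec& x, int H, int W, bool train,
                        double keep, SampleCache* sc) {
  fmat X = x.t();   // (1, H*W)
  fmat& K = net.Kbuf;
  fmat e1a = conv_relu(net.e1a, X, H, W, K);
  fmat e1b = conv_relu(net.e1b, e1a, H, W, K);
  umat i1; fmat p1 = maxpool(e1b, H, W, i1);
  int H2 = H / 2, W2 = W / 2;
  fmat e2a = conv_relu(net.e2a, p1, H2, W2, K);
  fmat e2b = conv_relu(net.e2b, e2a, H2, W2, K);
  umat i2; fmat p2 = maxpool(e2b, H2, W2, i2);
  int H3 = H2 / 2, W3 = W2 / 2;
  fmat e3a = conv_relu(net.e3a, p2, H3, W3, K);
  fmat e3b = conv_relu(net.e3b, e3a, H3, W3, K);
  umat i3; fmat p3 = maxpool(e3b, H3, W3, i3);
  int H4 = H3 / 2, W4 = W3 / 2;
  fmat e4a = conv_relu(net.e4a, p3, H4, W4, K);
  fmat e4b = conv_relu(net.e4b, e4a, H4, W4, K);
  // dropout in the two deepest encoder blocks
  fmat m4, e4d = e4b;
  if (train && keep < 1.0) {
    m4 = dropout_mask(net, e4b.n_rows, e4b.n_cols, keep);
    e4d = e4b % m4;
  }
  umat i4; fmat p4 = maxpool(e4d, H4, W4, i4);
  int H5 = H4 / 2, W5 = W4 / 2;
  fmat bna = conv_relu(net.bna, p4, H5, W5, K);
  fmat bnb = conv_relu(net.bnb, bna, H5, W5, K);
  fmat mbn, bnd = bnb;
  if (train && keep < 1.0) {
    mbn = dropout_mask(net, bnb.n_rows, bnb.n_cols, keep);
    bnd = bnb % mbn;
  }
  fmat up4 = upconv(net.u4, bnd, H5, W5);
  fmat cat4 = join_cols(up4, e4d);
  fmat d4a = conv_relu(net.d4a, cat4, H4, W4, K);
  fmat d4b = conv_relu(net.d4b, d4a, H4, W4, K);
  fmat up3 = upconv(net.u3, d4b, H4, W4);
  fmat cat3 = join_cols(up3, e3b);
  fmat d3a = conv_relu(net.d3a, cat3, H3, W3, K);
  fmat d3b = conv_relu(net.d3b, d3a, H3, W3, K);
  fmat up2 = upconv(net.u2, d3b, H3, W3);
  fmat cat2 = join_cols(up2, e2b);
  fmat d2a = conv_relu(net.d2a, cat2, H2, W2, K);
  fmat d2b = conv_relu(net.d2b, d2a, H2, W2, K);
  fmat up1 = upconv(net.u1, d2b, H2, W2);
  fmat cat1 = join_cols(up1, e1b);
  fmat d1a = conv_relu(net.d1a, cat1, H, W, K);
  fmat d1b = conv_relu(net.d1b, d1a, H, W, K);
  fmat logits = net.fin.W * d1b;
  logits.each_col() += net.fin.b;
  // per-pixel softmax over channels (rows)
  frowvec mx = max(logits, 0);
  logits.each_row() -= mx;
  fmat probs = exp(logits);
  frowvec s = sum(probs, 0);
  probs.each_row() /= s;

  if (sc) {
    sc->x = std::move(X);
    sc->e1a = std::move(e1a); sc->e1b = std::move(e1b); sc->p1 = std::move(p1); sc->i1 = std::move(i1);
    sc->e2a = std::move(e2a); sc->e2b = std::move(e2b); sc->p2 = std::move(p2); sc->i2 = std::move(i2);
    sc->e3a = std::move(e3a); sc->e3b = std::move(e3b); sc->p3 = std::move(p3); sc->i3 = std::move(i3);
    sc->e4a = std::move(e4a); sc->e4b = std::move(e4b); sc->e4d = std::move(e4d);
    sc->p4 = std::move(p4); sc->i4 = std::move(i4);
    sc->bna = std::move(bna); sc->bnb = std::move(bnb); sc->bnd = std::move(bnd);
    sc->u4 = std::move(up4); sc->d4a = std::move(d4a); sc->d4b = std::move(d4b);
    sc->u3 = std::move(up3); sc->d3a = std::move(d3a); sc->d3b = std::move(d3b);
    sc->u2 = std::move(up2); sc->d2a = std::move(d2a); sc->d2b = std::move(d2b);
    sc->u1 = std::move(up1); sc->d1a = std::move(d1a); sc->d1b = std::move(d1b);
    sc->probs = probs; sc->m4 = std::move(m4); sc->mbn = std::move(mbn); sc->H = H;
  }
  return probs;
}

static void backward_one(UNet& net, const fmat& dprobs, SampleCache& sc) {
  int H = sc.H, W = sc.H;
  fmat& K = net.Kbuf;
  // softmax backward
  const fmat& P = sc.probs;
  frowvec s = sum(dprobs % P, 0);
  fmat dlogits = P % (dprobs.each_row() - s);
  // final 1x1
  net.fin.db += sum(dlogits, 1);
  net.fin.dW += dlogits * sc.d1b.t();
  fmat dd1b = net.fin.W.t() * dlogits;
  fmat dd1a = conv_relu_backward(net.d1b, dd1b, sc.d1b, sc.d1a, H, W, K);
  fmat cat1 = join_cols(sc.u1, sc.e1b);
  fmat dcat1 = conv_relu_backward(net.d1a, dd1a, sc.d1a, cat1, H, W, K);
  int f = net.f;
  fmat dup1 = dcat1.rows(0, f - 1);
  fmat de1b_skip = dcat1.rows(f, 2 * f - 1);
  int H2 = H / 2, W2 = W / 2;
  fmat dd2b = upconv_backward(net.u1, dup1, sc.d2b, H2, W2);
  fmat dd2a = conv_relu_backward(net.d2b, dd2b, sc.d2b, sc.d2a, H2, W2, K);
  fmat cat2 = join_cols(sc.u2, sc.e2b);
  fmat dcat2 = conv_relu_backward(net.d2a, dd2a, sc.d2a, cat2, H2, W2, K);
  fmat dup2 = dcat2.rows(0, 2 * f - 1);
  fmat de2b_skip = dcat2.rows(2 * f, 4 * f - 1);
  int H3 = H2 / 2, W3 = W2 / 2;
  fmat dd3b = upconv_backward(net.u2, dup2, sc.d3b, H3, W3);
  fmat dd3a = conv_relu_backward(net.d3b, dd3b, sc.d3b, sc.d3a, H3, W3, K);
  fmat cat3 = join_cols(sc.u3, sc.e3b);
  fmat dcat3 = conv_relu_backward(net.d3a, dd3a, sc.d3a, cat3, H3, W3, K);
  fmat dup3 = dcat3.rows(0, 4 * f - 1);
  fmat de3b_skip = dcat3.rows(4 * f, 8 * f - 1);
  int H4 = H3 / 2, W4 = W3 / 2;
  fmat dd4b = upconv_backward(net.u3, dup3, sc.d4b, H4, W4);
  fmat dd4a = conv_relu_backward(net.d4b, dd4b, sc.d4b, sc.d4a, H4, W4, K);
  fmat cat4 = join_cols(sc.u4, sc.e4d);
  fmat dcat4 = conv_relu_backward(net.d4a, dd4a, sc.d4a, cat4, H4, W4, K);
  fmat dup4 = dcat4.rows(0, 8 * f - 1);
  fmat de4d_skip = dcat4.rows(8 * f, 16 * f - 1);
  int H5 = H4 / 2, W5 = W4 / 2;
  fmat dbnd = upconv_backward(net.u4, dup4, sc.bnd, H5, W5);
  fmat dbnb = sc.mbn.is_empty() ? dbnd : fmat(dbnd % sc.mbn);
  fmat dbna = conv_relu_backward(net.bnb, dbnb, sc.bnb, sc.bna, H5, W5, K);
  fmat dp4 = conv_relu_backward(net.bna, dbna, sc.bna, sc.p4, H5, W5, K);
  fmat de4d = maxpool_backward(dp4, sc.i4, H4 * W4) + de4d_skip;
  fmat de4b = sc.m4.is_empty() ? de4d : fmat(de4d % sc.m4);
  fmat de4a = conv_relu_backward(net.e4b, de4b, sc.e4b, sc.e4a, H4, W4, K);
  fmat dp3 = conv_relu_backward(net.e4a, de4a, sc.e4a, sc.p3, H4, W4, K);
  fmat de3b = maxpool_backward(dp3, sc.i3, H3 * W3) + de3b_skip;
  fmat de3a = conv_relu_backward(net.e3b, de3b, sc.e3b, sc.e3a, H3, W3, K);
  fmat dp2 = conv_relu_backward(net.e3a, de3a, sc.e3a, sc.p2, H3, W3, K);
  fmat de2b = maxpool_backward(dp2, sc.i2, H2 * W2) + de2b_skip;
  fmat de2a = conv_relu_backward(net.e2b, de2b, sc.e2b, sc.e2a, H2, W2, K);
  fmat dp1 = conv_relu_backward(net.e2a, de2a, sc.e2a, sc.p1, H2, W2, K);
  fmat de1b = maxpool_backward(dp1, sc.i1, H * W) + de1b_skip;
  fmat de1a = conv_relu_backward(net.e1b, de1b, sc.e1b, sc.e1a, H, W, K);
  conv_relu_backward(net.e1a, de1a, sc.e1a, sc.x, H, W, K);
}

// [[Rcpp::export]]
Rcpp::NumericVector unet_forward(SEXP ptr, Rcpp::NumericMatrix xbatch, int H,
                                 bool train, double keep_p) {
  Rcpp::XPtr<UNet> net(ptr);
  int n = xbatch.ncol();
  int HW = xbatch.nrow();
  if (HW != H * H) Rcpp::stop("patch pixel count does not match H^2");
  if (H % 16 != 0) Rcpp::stop("patch size must be divisible by 16 (four pooling stages)");
  int C = net->n_class;
  Rcpp::NumericVector out(Rcpp::Dimension(HW, C, n));
  if (train) {
    net->cache.assign(n, SampleCache());
    for (auto p : net->params()) { p->dW.zeros(); p->db.zeros(); }
  }
  for (int s = 0; s < n; ++s) {
    fvec x(HW);
    for (int i = 0; i < HW; ++i) x[i] = (float)xbatch(i, s);
    fmat probs = forward_one(*net, x, H, H, train, keep_p,
                             train ? &net->cache[s] : nullptr);
    // probs is (C, HW); emit (HW, C) slabs
    for (int c = 0; c < C; ++c)
      for (int i = 0; i < HW; ++i)
        out[(R_xlen_t)s * HW * C + (R_xlen_t)c * HW + i] = probs(c, i);
  }
  return out;
}

// [[Rcpp::export]]
void unet_backward(SEXP ptr, Rcpp::NumericVector dprobs) {
  Rcpp::XPtr<UNet> net(ptr);
  if (net->cache.empty()) Rcpp::stop("no cached forward pass; call unet_forward(train = TRUE) first");
  Rcpp::IntegerVector dims = dprobs.attr("dim");
  int HW = dims[0], C = dims[1], n = dims[2];
  if ((size_t)n != net->cache.size() || C != net->n_class)
    Rcpp::stop("gradient shape does not match the cached forward pass");
  for (int s = 0; s < n; ++s) {
    fmat dp(C, HW);
    for (int c = 0; c < C; ++c)
      for (int i = 0; i < HW; ++i)
        dp(c, i) = (float)dprobs[(R_xlen_t)s * HW * C + (R_xlen_t)c * HW + i];
    backward_one(*net, dp, net->cache[s]);
  }
}

// [[Rcpp::export]]
void unet_adam_step(SEXP ptr, double lr, double beta1, double beta2, double eps) {
  Rcpp::XPtr<UNet> net(ptr);
  net->t_adam += 1;
  double bc1 = 1.0 - std::pow(beta1, (double)net->t_adam);
  double bc2 = 1.0 - std::pow(beta2, (double)net->t_adam);
  for (auto p : net->params()) {
    p->mW = (float)beta1 * p->mW + (float)(1 - beta1) * p->dW;
    p->vW = (float)beta2 * p->vW + (float)(1 - beta2) * square(p->dW);
    p->W -= (float)lr * (p->mW / (float)bc1) / (sqrt(p->vW / (float)bc2) + (float)eps);
    p->mb = (float)beta1 * p->mb + (float)(1 - beta1) * p->db;
    p->vb = (float)beta2 * p->vb + (float)(1 - beta2) * square(p->db);
    p->b -= (float)lr * (p->mb / (float)bc1) / (sqrt(p->vb / (float)bc2) + (float)eps);
  }
  net->cache.clear();
}

// [[Rcpp::export]]
Rcpp::List unet_get_weights(SEXP ptr) {
  Rcpp::XPtr<UNet> net(ptr);
  Rcpp::List out;
  auto ps = net->params();
  for (size_t i = 0; i < ps.size(); ++i) {
    out.push_back(Rcpp::wrap(conv_to<mat>::from(ps[i]->W)));
    out.push_back(Rcpp::wrap(conv_to<vec>::from(ps[i]->b)));
  }
  out.attr("t_adam") = (double)net->t_adam;
  return out;
}

// [[Rcpp::export]]
void unet_set_weights(SEXP ptr, Rcpp::List weights) {
  Rcpp::XPtr<UNet> net(ptr);
  auto ps = net->params();
  if ((size_t)weights.size() != 2 * ps.size())
    Rcpp::stop("weight list length mismatch");
  for (size_t i = 0; i < ps.size(); ++i) {
    mat W = Rcpp::as<mat>(weights[2 * i]);
    vec b = Rcpp::as<vec>(weights[2 * i + 1]);
    if (W.n_rows != ps[i]->W.n_rows || W.n_cols != ps[i]->W.n_cols)
      Rcpp::stop("weight matrix %d shape mismatch", (int)i);
    ps[i]->W = conv_to<fmat>::from(W);
    ps[i]->b = conv_to<fvec>::from(b);
  }
  Rcpp::RObject t = weights.attr("t_adam");
  if (!t.isNULL()) net->t_adam = (long)Rcpp::as<double>(t);
}

// accumulated gradients in the same order as unet_get_weights (for
// finite-difference verification of the backward pass)
// [[Rcpp::export]]
Rcpp::List unet_get_grads(SEXP ptr) {
  Rcpp::XPtr<UNet> net(ptr);
  Rcpp::List out;
  for (auto p : net->params()) {
    out.push_back(Rcpp::wrap(conv_to<mat>::from(p->dW)));
    out.push_back(Rcpp::wrap(conv_to<vec>::from(p->db)));
  }
  return out;
}

// [[Rcpp::export]]
double unet_n_params(SEXP ptr) {
  Rcpp::XPtr<UNet> net(ptr);
  double n = 0;
  for (auto p : net->params()) n += p->W.n_elem + p->b.n_elem;
  return n;
}
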