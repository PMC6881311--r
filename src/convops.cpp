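// Compact CPU kernels for the U-net engine and the synthetic-texture toolkit.
//
// Layout conventions (shared with the R side):
//  * rasters/feature maps are arma::cube (rows = image rows, slices = channels),
//    i.e. R arrays with dim c(H, W, C);
//  * conv weights are a (k*k*Cin) x Cout matrix; feature row index
//    r = ci*k*k + dy*k + dx with kernel offsets dy, dx in 0..k-1 (pad = k/2);
//  * 2x2 transposed-conv weights are a Cin x (4*Cout) matrix; column index
//    c = co*4 + dy*2 + dx addresses the output 2x2 block.
// All arithmetic is single precision internally (halves memory traffic on the
// GEMMs that dominate training time); inputs/outputs cross to R as doubles.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static inline int reflect_idx(int t, int n) {
  // symmetric reflection with edge duplication, valid for any t
  if (n == 1) return 0;
  int period = 2 * n;
  t %= period;
  if (t < 0) t += period;
  return (t < n) ? t : period - 1 - t;
}

// im2col with 'same' zero padding for sample `b` of a batched cube
// (slices b*Ci .. (b+1)*Ci-1), written into the row block b*H*W of `col`
// which is (B*H*W) x (k*k*Ci)
static void im2col_same_into(const fcube& x, int k, int Ci, int b, fmat& col) {
  const int H = x.n_rows, W = x.n_cols, p = k / 2;
  const size_t HW = (size_t)H * W, off = (size_t)b * HW;
  for (int ci = 0; ci < Ci; ++ci) {
    const fmat& sl = x.slice(b * Ci + ci);
    for (int dy = 0; dy < k; ++dy) {
      for (int dx = 0; dx < k; ++dx) {
        const int r = (ci * k + dy) * k + dx;
        fmat view(col.colptr(r) + off, H, W, false, true);
        const int r0 = std::max(0, p - dy), r1 = std::min(H - 1, H - 1 + p - dy);
        const int c0 = std::max(0, p - dx), c1 = std::min(W - 1, W - 1 + p - dx);
        view.zeros();
        if (r0 <= r1 && c0 <= c1)
          view.submat(r0, c0, r1, c1) =
            sl.submat(r0 + dy - p, c0 + dx - p, r1 + dy - p, c1 + dx - p);
      }
    }
  }
}

// Batched same-padding convolution. x holds n_batch samples of Ci channels
// as consecutive slices; the result holds n_batch samples of Co channels.
// [[Rcpp::export]]
arma::cube cpp_conv2d_fw(const arma::cube& x, const arma::mat& Wm,
                         const arma::vec& b, int k, bool relu, int n_batch) {
  const int H = x.n_rows, W = x.n_cols, Co = Wm.n_cols;
  const int Ci = x.n_slices / n_batch;
  const size_t HW = (size_t)H * W;
  fcube xf = conv_to<fcube>::from(x);
  fmat col((size_t)n_batch * HW, (size_t)k * k * Ci);
  for (int bb = 0; bb < n_batch; ++bb) im2col_same_into(xf, k, Ci, bb, col);
  fmat Wf = conv_to<fmat>::from(Wm);
  fmat out = col * Wf;                       // (B*H*W) x Co
  fvec bf = conv_to<fvec>::from(b);
  out.each_row() += bf.t();
  if (relu) out.transform([](float v) { return v > 0.0f ? v : 0.0f; });
  cube res(H, W, (size_t)n_batch * Co);
  for (int bb = 0; bb < n_batch; ++bb) {
    for (int co = 0; co < Co; ++co) {
      fmat view(out.colptr(co) + (size_t)bb * HW, H, W, false, true);
      res.slice(bb * Co + co) = conv_to<mat>::from(view);
    }
  }
  return res;
}

// Backward pass of the batched convolution. `act` is the forward output
// (post-ReLU when relu = true) used to gate the incoming gradient; gW/gb
// are summed over the batch.
// [[Rcpp::export]]
Rcpp::List cpp_conv2d_bw(const arma::cube& x, const arma::mat& Wm,
                         const arma::cube& gout, int k, bool relu,
                         const arma::cube& act, int n_batch) {
  const int H = x.n_rows, W = x.n_cols;
  const int Ci = x.n_slices / n_batch, Co = Wm.n_cols, p = k / 2;
  const size_t HW = (size_t)H * W;
  fcube xf = conv_to<fcube>::from(x);
  fcube gf = conv_to<fcube>::from(gout);
  if (relu) {
    fcube af = conv_to<fcube>::from(act);
    for (uword i = 0; i < gf.n_elem; ++i)
      if (af(i) <= 0.0f) gf(i) = 0.0f;
  }
  fmat goutT((size_t)n_batch * HW, Co);
  for (int bb = 0; bb < n_batch; ++bb)
    for (int co = 0; co < Co; ++co)
      std::memcpy(goutT.colptr(co) + (size_t)bb * HW,
                  gf.slice(bb * Co + co).memptr(), sizeof(float) * HW);
  fmat col((size_t)n_batch * HW, (size_t)k * k * Ci);
  for (int bb = 0; bb < n_batch; ++bb) im2col_same_into(xf, k, Ci, bb, col);
  fmat Wf = conv_to<fmat>::from(Wm);
  fmat gW = col.t() * goutT;                 // (k*k*Ci) x Co, batch-summed
  fvec gb = sum(goutT, 0).t();
  fmat gcol = goutT * Wf.t();                // (B*H*W) x (k*k*Ci)
  fcube gx(H, W, (size_t)n_batch * Ci, fill::zeros);
  for (int bb = 0; bb < n_batch; ++bb) {
    for (int ci = 0; ci < Ci; ++ci) {
      for (int dy = 0; dy < k; ++dy) {
        for (int dx = 0; dx < k; ++dx) {
          const int r = (ci * k + dy) * k + dx;
          fmat view(gcol.colptr(r) + (size_t)bb * HW, H, W, false, true);
          const int r0 = std::max(0, p - dy), r1 = std::min(H - 1, H - 1 + p - dy);
          const int c0 = std::max(0, p - dx), c1 = std::min(W - 1, W - 1 + p - dx);
          if (r0 <= r1 && c0 <= c1)
            gx.slice(bb * Ci + ci)
              .submat(r0 + dy - p, c0 + dx - p, r1 + dy - p, c1 + dx - p)
              += view.submat(r0, c0, r1, c1);
        }
      }
    }
  }
  return Rcpp::List::create(
    Rcpp::Named("gx") = conv_to<cube>::from(gx),
    Rcpp::Named("gW") = conv_to<mat>::from(gW),
    Rcpp::Named("gb") = conv_to<vec>::from(gb));
}

// [[Rcpp::export]]
Rcpp::List cpp_maxpool2_fw(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int h = H / 2, w = W / 2;
  cube out(h, w, C);
  Rcpp::IntegerVector idx(h * (size_t)w * C);   // linear index within slice
  size_t q = 0;
  for (int c = 0; c < C; ++c) {
    const mat& sl = x.slice(c);
    for (int cc = 0; cc < w; ++cc) {
      for (int rr = 0; rr < h; ++rr) {
        const int R = 2 * rr, Cc = 2 * cc;
        double best = sl(R, Cc); int bi = R + Cc * H;
        if (sl(R + 1, Cc)     > best) { best = sl(R + 1, Cc);     bi = R + 1 + Cc * H; }
        if (sl(R,     Cc + 1) > best) { best = sl(R,     Cc + 1); bi = R + (Cc + 1) * H; }
        if (sl(R + 1, Cc + 1) > best) { best = sl(R + 1, Cc + 1); bi = R + 1 + (Cc + 1) * H; }
        out(rr, cc, c) = best;
        idx[c * (size_t)h * w + cc * (size_t)h + rr] = bi;
      }
    }
  }
  (void)q;
  return Rcpp::List::create(Rcpp::Named("out") = out, Rcpp::Named("idx") = idx);
}

// [[Rcpp::export]]
arma::cube cpp_maxpool2_bw(const Rcpp::IntegerVector& idx, const arma::cube& gout,
                           int H, int W) {
  const int h = gout.n_rows, w = gout.n_cols, C = gout.n_slices;
  cube gx(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    double* dst = gx.slice(c).memptr();
    const mat& g = gout.slice(c);
    for (int cc = 0; cc < w; ++cc)
      for (int rr = 0; rr < h; ++rr)
        dst[idx[c * (size_t)h * w + cc * (size_t)h + rr]] += g(rr, cc);
  }
  return gx;
}

// 2x2 stride-2 transposed convolution (up-convolution), batched like conv
// [[Rcpp::export]]
arma::cube cpp_upconv2_fw(const arma::cube& x, const arma::mat& Wm,
                          const arma::vec& b, int n_batch) {
  const int H = x.n_rows, W = x.n_cols, Ci = x.n_slices / n_batch;
  const int Co = Wm.n_cols / 4;
  const size_t HW = (size_t)H * W;
  fmat xT((size_t)n_batch * HW, Ci);
  fcube xf = conv_to<fcube>::from(x);
  for (int bb = 0; bb < n_batch; ++bb)
    for (int ci = 0; ci < Ci; ++ci)
      std::memcpy(xT.colptr(ci) + (size_t)bb * HW,
                  xf.slice(bb * Ci + ci).memptr(), sizeof(float) * HW);
  fmat Wf = conv_to<fmat>::from(Wm);
  fmat res = xT * Wf;                         // (B*H*W) x (4*Co)
  cube out(2 * H, 2 * W, (size_t)n_batch * Co);
  for (int bb = 0; bb < n_batch; ++bb) {
    for (int co = 0; co < Co; ++co) {
      mat& osl = out.slice(bb * Co + co);
      for (int dy = 0; dy < 2; ++dy) {
        for (int dx = 0; dx < 2; ++dx) {
          const int col = co * 4 + dy * 2 + dx;
          fmat view(res.colptr(col) + (size_t)bb * HW, H, W, false, true);
          for (int cc = 0; cc < W; ++cc)
            for (int rr = 0; rr < H; ++rr)
              osl(2 * rr + dy, 2 * cc + dx) = view(rr, cc) + b[co];
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
Rcpp::List cpp_upconv2_bw(const arma::cube& x, const arma::mat& Wm,
                          const arma::cube& gout, int n_batch) {
  const int H = x.n_rows, W = x.n_cols, Ci = x.n_slices / n_batch;
  const int Co = Wm.n_cols / 4;
  const size_t HW = (size_t)H * W;
  fcube gf = conv_to<fcube>::from(gout);
  fmat gres((size_t)n_batch * HW, 4 * Co);
  vec gb(Co, fill::zeros);
  for (int bb = 0; bb < n_batch; ++bb) {
    for (int co = 0; co < Co; ++co) {
      const fmat& gsl = gf.slice(bb * Co + co);
      for (int dy = 0; dy < 2; ++dy) {
        for (int dx = 0; dx < 2; ++dx) {
          const int col = co * 4 + dy * 2 + dx;
          fmat view(gres.colptr(col) + (size_t)bb * HW, H, W, false, true);
          for (int cc = 0; cc < W; ++cc)
            for (int rr = 0; rr < H; ++rr)
              view(rr, cc) = gsl(2 * rr + dy, 2 * cc + dx);
        }
      }
      gb[co] += accu(conv_to<mat>::from(gsl));
    }
  }
  fmat xT((size_t)n_batch * HW, Ci);
  fcube xf = conv_to<fcube>::from(x);
  for (int bb = 0; bb < n_batch; ++bb)
    for (int ci = 0; ci < Ci; ++ci)
      std::memcpy(xT.colptr(ci) + (size_t)bb * HW,
                  xf.slice(bb * Ci + ci).memptr(), sizeof(float) * HW);
  fmat Wf = conv_to<fmat>::from(Wm);
  fmat gW = xT.t() * gres;                    // Ci x (4*Co), batch-summed
  fmat gxT = gres * Wf.t();                   // (B*H*W) x Ci
  cube gx(H, W, (size_t)n_batch * Ci);
  for (int bb = 0; bb < n_batch; ++bb) {
    for (int ci = 0; ci < Ci; ++ci) {
      fmat view(gxT.colptr(ci) + (size_t)bb * HW, H, W, false, true);
      gx.slice(bb * Ci + ci) = conv_to<mat>::from(view);
    }
  }
  return Rcpp::List::create(
    Rcpp::Named("gx") = gx,
    Rcpp::Named("gW") = conv_to<mat>::from(gW),
    Rcpp::Named("gb") = gb);
}

// ---------------------------------------------------------------------------
// Fused U-net engine: the whole forward/backward walk in single precision,
// with the im2col matrices and activations of the forward pass cached in an
// external context so the backward pass re-uses them. Layer traversal order
// (matching unet_layer_order() on the R side):
//   enc1_conv1 .. enc1_convn, ..., encL_convn,
//   up{L-1}, dec{L-1}_conv1 .. dec{L-1}_convn, ..., up1, dec1_conv*, out.
// ---------------------------------------------------------------------------

struct UnetCtx {
  std::vector<fmat> cols;        // per conv layer: im2col of its input
  std::vector<Cube<unsigned char>> acts;  // per conv layer: ReLU gate mask
  std::vector<Rcpp::IntegerVector> pool_idx;
  std::vector<std::pair<int, int>> pool_dims;
  std::vector<fmat> up_xT;       // per upconv: input as (B*HW) x Ci
  std::vector<fcube> skips;      // encoder outputs feeding skip connections
  int H = 0, W = 0, n_batch = 1;
};

static fmat im2col_batch(const fcube& x, int k, int Ci, int n_batch) {
  const size_t HW = (size_t)x.n_rows * x.n_cols;
  fmat col((size_t)n_batch * HW, (size_t)k * k * Ci);
  for (int bb = 0; bb < n_batch; ++bb) im2col_same_into(x, k, Ci, bb, col);
  return col;
}

static fcube conv_apply(const fmat& col, const fmat& Wf, const fvec& bf,
                        int H, int W, int n_batch, bool relu) {
  const int Co = Wf.n_cols;
  const size_t HW = (size_t)H * W;
  fmat out = col * Wf;
  out.each_row() += bf.t();
  if (relu) out.transform([](float v) { return v > 0.0f ? v : 0.0f; });
  fcube res(H, W, (size_t)n_batch * Co);
  for (int bb = 0; bb < n_batch; ++bb)
    for (int co = 0; co < Co; ++co)
      std::memcpy(res.slice(bb * Co + co).memptr(),
                  out.colptr(co) + (size_t)bb * HW, sizeof(float) * HW);
  return res;
}

// col2im accumulate: fold gcol ((B*HW) x k2Ci) back onto input geometry
static fcube col2im_batch(const fmat& gcol, int k, int H, int W, int Ci,
                          int n_batch) {
  const int p = k / 2;
  const size_t HW = (size_t)H * W;
  fcube gx(H, W, (size_t)n_batch * Ci, fill::zeros);
  for (int bb = 0; bb < n_batch; ++bb) {
    for (int ci = 0; ci < Ci; ++ci) {
      for (int dy = 0; dy < k; ++dy) {
        for (int dx = 0; dx < k; ++dx) {
          const int r = (ci * k + dy) * k + dx;
          const fmat view(const_cast<float*>(gcol.colptr(r)) + (size_t)bb * HW,
                          H, W, false, true);
          const int r0 = std::max(0, p - dy), r1 = std::min(H - 1, H - 1 + p - dy);
          const int c0 = std::max(0, p - dx), c1 = std::min(W - 1, W - 1 + p - dx);
          if (r0 <= r1 && c0 <= c1)
            gx.slice(bb * Ci + ci)
              .submat(r0 + dy - p, c0 + dx - p, r1 + dy - p, c1 + dx - p)
              += view.submat(r0, c0, r1, c1);
        }
      }
    }
  }
  return gx;
}

static fmat to_fmat(const Rcpp::NumericMatrix& m) {
  fmat f(m.nrow(), m.ncol());
  std::copy(m.begin(), m.end(), f.memptr());
  return f;
}

static fvec to_fvec(const Rcpp::NumericVector& v) {
  fvec f(v.size());
  std::copy(v.begin(), v.end(), f.memptr());
  return f;
}

static fcube maxpool_ctx(const fcube& x, Rcpp::IntegerVector& idx_out) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int h = H / 2, w = W / 2;
  fcube out(h, w, C);
  Rcpp::IntegerVector idx((size_t)h * w * C);
  for (int c = 0; c < C; ++c) {
    const fmat& sl = x.slice(c);
    for (int cc = 0; cc < w; ++cc) {
      for (int rr = 0; rr < h; ++rr) {
        const int R = 2 * rr, Cc = 2 * cc;
        float best = sl(R, Cc); int bi = R + Cc * H;
        if (sl(R + 1, Cc)     > best) { best = sl(R + 1, Cc);     bi = R + 1 + Cc * H; }
        if (sl(R,     Cc + 1) > best) { best = sl(R,     Cc + 1); bi = R + (Cc + 1) * H; }
        if (sl(R + 1, Cc + 1) > best) { best = sl(R + 1, Cc + 1); bi = R + 1 + (Cc + 1) * H; }
        out(rr, cc, c) = best;
        idx[c * (size_t)h * w + cc * (size_t)h + rr] = bi;
      }
    }
  }
  idx_out = idx;
  return out;
}

static fmat build_xT(const fcube& x, int Ci, int n_batch) {
  const size_t HW = (size_t)x.n_rows * x.n_cols;
  fmat xT((size_t)n_batch * HW, Ci);
  for (int bb = 0; bb < n_batch; ++bb)
    for (int ci = 0; ci < Ci; ++ci)
      std::memcpy(xT.colptr(ci) + (size_t)bb * HW,
                  x.slice(bb * Ci + ci).memptr(), sizeof(float) * HW);
  return xT;
}

// [[Rcpp::export]]
Rcpp::List cpp_unet_fw(const arma::cube& x, const Rcpp::List& weights,
                       int levels, int convs_per_level, int k, int n_batch,
                       bool keep_ctx) {
  const int H = x.n_rows, W = x.n_cols;
  const int Cin_total = x.n_slices;
  const int Cin = Cin_total / n_batch;
  auto ctx = new UnetCtx();
  ctx->H = H; ctx->W = W; ctx->n_batch = n_batch;
  const int n_convs = (2 * levels - 1) * convs_per_level + 1;
  ctx->cols.reserve(n_convs);
  ctx->acts.reserve(n_convs);
  ctx->skips.reserve(levels);
  ctx->up_xT.reserve(levels);
  ctx->pool_idx.reserve(levels);
  ctx->pool_dims.reserve(levels);
  fcube cur(H, W, Cin_total);
  for (uword i = 0; i < x.n_elem; ++i) cur(i) = (float)x(i);
  int wi = 0;
  auto conv_layer = [&](fcube& input, bool relu) {
    Rcpp::List lay = weights[wi++];
    fmat Wf = to_fmat(lay["W"]);
    fvec bf = to_fvec(lay["b"]);
    const int kk = (int)std::lround(std::sqrt((double)Wf.n_rows /
                     (input.n_slices / n_batch)));
    fmat col = im2col_batch(input, kk, input.n_slices / n_batch, n_batch);
    fcube out = conv_apply(col, Wf, bf, input.n_rows, input.n_cols, n_batch,
                           relu);
    if (keep_ctx) {
      ctx->cols.push_back(std::move(col));
      Cube<unsigned char> gate(out.n_rows, out.n_cols, out.n_slices);
      for (uword i = 0; i < out.n_elem; ++i) gate(i) = out(i) > 0.0f;
      ctx->acts.push_back(std::move(gate));
    }
    return out;
  };
  for (int lv = 0; lv < levels; ++lv) {
    for (int j = 0; j < convs_per_level; ++j) cur = conv_layer(cur, true);
    if (lv < levels - 1) {
      if (keep_ctx) ctx->skips.push_back(cur);
      Rcpp::IntegerVector idx;
      fcube pooled = maxpool_ctx(cur, idx);
      if (keep_ctx) { ctx->pool_idx.push_back(idx);
                      ctx->pool_dims.push_back({(int)cur.n_rows, (int)cur.n_cols}); }
      if (!keep_ctx) ctx->skips.push_back(std::move(cur));   // still needed for concat
      cur = std::move(pooled);
    }
  }
  for (int lv = levels - 2; lv >= 0; --lv) {
    Rcpp::List lay = weights[wi++];
    fmat Wf = to_fmat(lay["W"]);
    fvec bf = to_fvec(lay["b"]);
    const int Ci_up = cur.n_slices / n_batch;
    const int Co = Wf.n_cols / 4;
    const int h = cur.n_rows, w = cur.n_cols;
    const size_t HW = (size_t)h * w;
    fmat xT = build_xT(cur, Ci_up, n_batch);
    fmat res = xT * Wf;
    fcube up(2 * h, 2 * w, (size_t)n_batch * Co);
    for (int bb = 0; bb < n_batch; ++bb) {
      for (int co = 0; co < Co; ++co) {
        fmat& osl = up.slice(bb * Co + co);
        for (int dy = 0; dy < 2; ++dy)
          for (int dx = 0; dx < 2; ++dx) {
            const fmat view(const_cast<float*>(res.colptr(co * 4 + dy * 2 + dx))
                            + (size_t)bb * HW, h, w, false, true);
            for (int cc2 = 0; cc2 < w; ++cc2)
              for (int rr2 = 0; rr2 < h; ++rr2)
                osl(2 * rr2 + dy, 2 * cc2 + dx) = view(rr2, cc2) + bf[co];
          }
      }
    }
    if (keep_ctx) ctx->up_xT.push_back(std::move(xT));
    // concat skip (encoder level lv) with up, per sample
    const fcube& sk = ctx->skips[lv];
    const int Cs = sk.n_slices / n_batch;
    fcube cat(up.n_rows, up.n_cols, (size_t)n_batch * (Cs + Co));
    for (int bb = 0; bb < n_batch; ++bb) {
      for (int c = 0; c < Cs; ++c)
        cat.slice(bb * (Cs + Co) + c) = sk.slice(bb * Cs + c);
      for (int c = 0; c < Co; ++c)
        cat.slice(bb * (Cs + Co) + Cs + c) = up.slice(bb * Co + c);
    }
    cur = std::move(cat);
    for (int j = 0; j < convs_per_level; ++j) cur = conv_layer(cur, true);
  }
  cur = conv_layer(cur, false);     // 1x1 output convolution, linear
  // sigmoid probabilities, one slice per sample
  cube p(H, W, n_batch);
  for (uword i = 0; i < cur.n_elem; ++i)
    p(i) = 1.0 / (1.0 + std::exp(-(double)cur(i)));
  Rcpp::List out = Rcpp::List::create(Rcpp::Named("p") = p);
  if (keep_ctx) {
    out["ctx"] = Rcpp::XPtr<UnetCtx>(ctx, true);
  } else {
    delete ctx;
  }
  return out;
}

// [[Rcpp::export]]
Rcpp::List cpp_unet_bw(SEXP ctx_ptr, const Rcpp::List& weights,
                       const arma::cube& p, const arma::cube& gp,
                       int levels, int convs_per_level, int k) {
  Rcpp::XPtr<UnetCtx> ctx(ctx_ptr);
  const int nb = ctx->n_batch;
  const int n_layers = (int)weights.size();
  std::vector<Rcpp::List> grads(n_layers);
  int wi = n_layers - 1;            // walk layers in reverse
  int conv_i = (int)ctx->cols.size() - 1;
  int up_i = (int)ctx->up_xT.size() - 1;
  int pool_i = (int)ctx->pool_idx.size() - 1;

  // dL/dz at the sigmoid head
  const int H = ctx->H, W = ctx->W;
  fcube gcur(H, W, nb);
  for (uword i = 0; i < gcur.n_elem; ++i)
    gcur(i) = (float)(gp(i) * p(i) * (1.0 - p(i)));

  auto conv_back = [&](fcube& gout, bool relu, int kk) {
    Rcpp::List lay = weights[wi];
    fmat Wf = to_fmat(lay["W"]);
    const fmat& col = ctx->cols[conv_i];
    const Cube<unsigned char>& act = ctx->acts[conv_i];
    const int Co = Wf.n_cols;
    const int h = gout.n_rows, w = gout.n_cols;
    const size_t HW = (size_t)h * w;
    if (relu)
      for (uword i = 0; i < gout.n_elem; ++i)
        if (!act(i)) gout(i) = 0.0f;
    fmat goutT((size_t)nb * HW, Co);
    for (int bb = 0; bb < nb; ++bb)
      for (int co = 0; co < Co; ++co)
        std::memcpy(goutT.colptr(co) + (size_t)bb * HW,
                    gout.slice(bb * Co + co).memptr(), sizeof(float) * HW);
    fmat gW = col.t() * goutT;
    fvec gb = sum(goutT, 0).t();
    grads[wi] = Rcpp::List::create(
      Rcpp::Named("W") = conv_to<mat>::from(gW),
      Rcpp::Named("b") = conv_to<vec>::from(gb));
    fmat gcol = goutT * Wf.t();
    const int Ci_in = (int)Wf.n_rows / (kk * kk);
    fcube gx = col2im_batch(gcol, kk, h, w, Ci_in, nb);
    wi--; conv_i--;
    return gx;
  };

  fcube g = conv_back(gcur, false, 1);    // output 1x1 conv
  std::vector<fcube> gskip(levels);
  for (int lv = 0; lv < levels - 1; ++lv) {
    for (int j = 0; j < convs_per_level; ++j) g = conv_back(g, true, k);
    // split concat gradient into skip and up parts
    const int Ctot = g.n_slices / nb;
    const int Cs = (int)ctx->skips[lv].n_slices / nb;
    const int Co = Ctot - Cs;
    const int h = g.n_rows, w = g.n_cols;
    fcube gsk(h, w, (size_t)nb * Cs), gup(h, w, (size_t)nb * Co);
    for (int bb = 0; bb < nb; ++bb) {
      for (int c = 0; c < Cs; ++c)
        gsk.slice(bb * Cs + c) = g.slice(bb * Ctot + c);
      for (int c = 0; c < Co; ++c)
        gup.slice(bb * Co + c) = g.slice(bb * Ctot + Cs + c);
    }
    gskip[lv] = std::move(gsk);
    // upconv backward
    Rcpp::List lay = weights[wi];
    fmat Wf = to_fmat(lay["W"]);
    const fmat& xT = ctx->up_xT[up_i];
    const int h2 = h / 2, w2 = w / 2;
    const size_t HW2 = (size_t)h2 * w2;
    fmat gres((size_t)nb * HW2, 4 * Co);
    vec gb(Co, fill::zeros);
    for (int bb = 0; bb < nb; ++bb) {
      for (int co = 0; co < Co; ++co) {
        const fmat& gsl = gup.slice(bb * Co + co);
        for (int dy = 0; dy < 2; ++dy)
          for (int dx = 0; dx < 2; ++dx) {
            fmat view(gres.colptr(co * 4 + dy * 2 + dx) + (size_t)bb * HW2,
                      h2, w2, false, true);
            for (int cc2 = 0; cc2 < w2; ++cc2)
              for (int rr2 = 0; rr2 < h2; ++rr2)
                view(rr2, cc2) = gsl(2 * rr2 + dy, 2 * cc2 + dx);
          }
        gb[co] += accu(conv_to<mat>::from(gsl));
      }
    }
    fmat gW = xT.t() * gres;
    grads[wi] = Rcpp::List::create(
      Rcpp::Named("W") = conv_to<mat>::from(gW),
      Rcpp::Named("b") = gb);
    fmat gxT = gres * Wf.t();
    const int Ci_up = (int)Wf.n_rows;
    fcube gx(h2, w2, (size_t)nb * Ci_up);
    for (int bb = 0; bb < nb; ++bb)
      for (int ci = 0; ci < Ci_up; ++ci)
        std::memcpy(gx.slice(bb * Ci_up + ci).memptr(),
                    gxT.colptr(ci) + (size_t)bb * HW2, sizeof(float) * HW2);
    wi--; up_i--;
    g = std::move(gx);
  }
  // encoder, deepest level first
  for (int lv = levels - 1; lv >= 0; --lv) {
    if (lv < levels - 1) {
      // un-pool and add the skip gradient
      const auto dims = ctx->pool_dims[pool_i];
      const Rcpp::IntegerVector& idx = ctx->pool_idx[pool_i];
      const int Hp = dims.first, Wp = dims.second;
      const int h = g.n_rows, w = g.n_cols, C = g.n_slices;
      fcube gxp(Hp, Wp, C, fill::zeros);
      for (int c = 0; c < C; ++c) {
        float* dst = gxp.slice(c).memptr();
        const fmat& gsl = g.slice(c);
        for (int cc2 = 0; cc2 < w; ++cc2)
          for (int rr2 = 0; rr2 < h; ++rr2)
            dst[idx[c * (size_t)h * w + cc2 * (size_t)h + rr2]] += gsl(rr2, cc2);
      }
      gxp += gskip[lv];
      pool_i--;
      g = std::move(gxp);
    }
    for (int j = 0; j < convs_per_level; ++j) g = conv_back(g, true, k);
  }
  // release the cached forward context now rather than at GC time: the
  // buffers are large and invisible to R's collector
  ctx->cols.clear(); ctx->cols.shrink_to_fit();
  ctx->acts.clear(); ctx->acts.shrink_to_fit();
  ctx->skips.clear(); ctx->skips.shrink_to_fit();
  ctx->up_xT.clear(); ctx->up_xT.shrink_to_fit();
  ctx->pool_idx.clear();
  ctx->pool_dims.clear();
  return Rcpp::wrap(grads);
}

// Affine warp by inverse mapping: A (2x3) sends output (row, col) to source
// (row, col): sr = A(0,0)*r + A(0,1)*c + A(0,2); sc = A(1,0)*r + A(1,1)*c + A(1,2).
// method: 0 nearest neighbour, 1 bilinear. Out-of-range samples reflect at the
// borders (edge pixels duplicated), so no artificial background value enters.
// [[Rcpp::export]]
arma::cube cpp_warp_affine(const arma::cube& x, const arma::mat& A, int method) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  cube out(H, W, C);
  for (int cc = 0; cc < W; ++cc) {
    for (int rr = 0; rr < H; ++rr) {
      const double sr = A(0, 0) * rr + A(0, 1) * cc + A(0, 2);
      const double sc = A(1, 0) * rr + A(1, 1) * cc + A(1, 2);
      if (method == 0) {
        const int ir = reflect_idx((int)std::lround(sr), H);
        const int ic = reflect_idx((int)std::lround(sc), W);
        for (int ch = 0; ch < C; ++ch) out(rr, cc, ch) = x(ir, ic, ch);
      } else {
        const int r0 = (int)std::floor(sr), c0 = (int)std::floor(sc);
        const double fr = sr - r0, fc = sc - c0;
        const int ra = reflect_idx(r0, H), rb = reflect_idx(r0 + 1, H);
        const int ca = reflect_idx(c0, W), cb = reflect_idx(c0 + 1, W);
        for (int ch = 0; ch < C; ++ch) {
          const double v =
            (1 - fr) * ((1 - fc) * x(ra, ca, ch) + fc * x(ra, cb, ch)) +
            fr       * ((1 - fc) * x(rb, ca, ch) + fc * x(rb, cb, ch));
          out(rr, cc, ch) = v;
        }
      }
    }
  }
  return out;
}

static mat blur_1d_rows(const mat& x, const vec& ker) {
  const int H = x.n_rows, W = x.n_cols, R = ((int)ker.n_elem - 1) / 2;
  mat out(H, W);
  for (int cc = 0; cc < W; ++cc) {
    for (int rr = 0; rr < H; ++rr) {
      double s = 0.0;
      for (int t = -R; t <= R; ++t)
        s += ker[t + R] * x(reflect_idx(rr + t, H), cc);
      out(rr, cc) = s;
    }
  }
  return out;
}

// Separable Gaussian blur, reflected borders, kernel truncated at 3 sigma.
// [[Rcpp::export]]
arma::mat cpp_gaussian_blur(const arma::mat& x, double sigma) {
  if (sigma <= 0) return x;
  const int R = std::max(1, (int)std::ceil(3.0 * sigma));
  vec ker(2 * R + 1);
  for (int t = -R; t <= R; ++t) ker[t + R] = std::exp(-0.5 * t * t / (sigma * sigma));
  ker /= accu(ker);
  mat tmp = blur_1d_rows(x, ker);
  return blur_1d_rows(tmp.t(), ker).t();
}

// Axis-wise separable Gaussian blur with distinct row/col sigmas
// (anisotropic grain before rotation of the field).
// [[Rcpp::export]]
arma::mat cpp_gaussian_blur_aniso(const arma::mat& x, double sig_r, double sig_c) {
  auto make_ker = [](double sigma) {
    const int R = std::max(1, (int)std::ceil(3.0 * sigma));
    vec ker(2 * R + 1);
    for (int t = -R; t <= R; ++t)
      ker[t + R] = std::exp(-0.5 * t * t / (sigma * sigma));
    ker /= accu(ker);
    return ker;
  };
  mat tmp = (sig_r > 0) ? blur_1d_rows(x, make_ker(sig_r)) : x;
  if (sig_c > 0) tmp = blur_1d_rows(tmp.t(), make_ker(sig_c)).t();
  return tmp;
}

// Local standard deviation over a (2r+1)^2 box, reflected borders.
// [[Rcpp::export]]
arma::mat cpp_local_sd(const arma::mat& x, int radius) {
  const int n = 2 * radius + 1;
  vec ker(n, fill::value(1.0 / n));
  mat m  = blur_1d_rows(blur_1d_rows(x, ker).t(), ker).t();
  mat m2 = blur_1d_rows(blur_1d_rows(square(x), ker).t(), ker).t();
  mat v = m2 - square(m);
  v.transform([](double z) { return z > 0 ? std::sqrt(z) : 0.0; });
  return v;
}
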