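// Low-level numeric kernels for the vineseg network and geometry code.
//
// Feature maps are R arrays with dim (H, W, C), column-major.
// Convolution weights have dim (kh, kw, Cin, Cout).
// All pixel geometry is 0-based continuous: pixel (row r, col c) covers
// x in [c, c+1) and y in [r, r+1); its center is (c + 0.5, r + 0.5).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// ---------------------------------------------------------------------------
// conv2d via im2col + GEMM
// ---------------------------------------------------------------------------

static arma::mat im2col_hwc(const double* xp, int H, int W, int C,
                            int kh, int kw, int stride, int pad,
                            int Ho, int Wo) {
  arma::mat col(kh * kw * C, (arma::uword)Ho * Wo, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const double* xc = xp + (size_t)H * W * c;
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        int r = i + kh * (j + kw * c);
        for (int wo = 0; wo < Wo; ++wo) {
          int xw = wo * stride - pad + j;
          if (xw < 0 || xw >= W) continue;
          const double* xcol = xc + (size_t)H * xw;
          for (int ho = 0; ho < Ho; ++ho) {
            int xh = ho * stride - pad + i;
            if (xh < 0 || xh >= H) continue;
            col(r, ho + (arma::uword)Ho * wo) = xcol[xh];
          }
        }
      }
    }
  }
  return col;
}

static void col2im_hwc(const arma::mat& col, double* gx, int H, int W, int C,
                       int kh, int kw, int stride, int pad, int Ho, int Wo) {
  for (int c = 0; c < C; ++c) {
    double* xc = gx + (size_t)H * W * c;
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        int r = i + kh * (j + kw * c);
        for (int wo = 0; wo < Wo; ++wo) {
          int xw = wo * stride - pad + j;
          if (xw < 0 || xw >= W) continue;
          double* xcol = xc + (size_t)H * xw;
          for (int ho = 0; ho < Ho; ++ho) {
            int xh = ho * stride - pad + i;
            if (xh < 0 || xh >= H) continue;
            xcol[xh] += col(r, ho + (arma::uword)Ho * wo);
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fwd(NumericVector x, NumericVector w,
                             Nullable<NumericVector> bias,
                             int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2];
  int kh = wd[0], kw = wd[1], ci = wd[2], co = wd[3];
  if (ci != C) stop("conv2d: input has %d channels, weight expects %d", C, ci);
  int Ho = (H + 2 * pad - kh) / stride + 1;
  int Wo = (W + 2 * pad - kw) / stride + 1;
  if (Ho < 1 || Wo < 1) stop("conv2d: output would be empty");
  arma::mat col = im2col_hwc(x.begin(), H, W, C, kh, kw, stride, pad, Ho, Wo);
  arma::mat Wm(const_cast<double*>(w.begin()), (arma::uword)kh * kw * ci, co,
               false, true);
  arma::mat out = col.t() * Wm;  // (Ho*Wo) x co
  if (bias.isNotNull()) {
    NumericVector b(bias);
    for (int k = 0; k < co; ++k) out.col(k) += b[k];
  }
  NumericVector y(out.begin(), out.end());
  y.attr("dim") = IntegerVector::create(Ho, Wo, co);
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(NumericVector x, NumericVector w, NumericVector gy,
                    int stride, int pad, bool has_bias) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  IntegerVector yd = gy.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2];
  int kh = wd[0], kw = wd[1], ci = wd[2], co = wd[3];
  int Ho = yd[0], Wo = yd[1];
  arma::uword K = (arma::uword)kh * kw * ci, N = (arma::uword)Ho * Wo;
  arma::mat col = im2col_hwc(x.begin(), H, W, C, kh, kw, stride, pad, Ho, Wo);
  arma::mat Gm(const_cast<double*>(gy.begin()), N, co, false, true);
  arma::mat Wm(const_cast<double*>(w.begin()), K, co, false, true);

  arma::mat gwm = col * Gm;                    // K x co
  arma::mat gcol = Wm * Gm.t();                // K x N
  NumericVector gx(x.size());
  gx.attr("dim") = xd;
  std::fill(gx.begin(), gx.end(), 0.0);
  col2im_hwc(gcol, gx.begin(), H, W, C, kh, kw, stride, pad, Ho, Wo);

  NumericVector gw(gwm.begin(), gwm.end());
  gw.attr("dim") = wd;
  List out = List::create(_["gx"] = gx, _["gw"] = gw);
  if (has_bias) {
    arma::rowvec gb = arma::sum(Gm, 0);
    out["gb"] = NumericVector(gb.begin(), gb.end());
  }
  return out;
}

// ---------------------------------------------------------------------------
// max pooling
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_maxpool_fwd(NumericVector x, int k, int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2];
  int Ho = (H + 2 * pad - k) / stride + 1;
  int Wo = (W + 2 * pad - k) / stride + 1;
  NumericVector y((size_t)Ho * Wo * C);
  IntegerVector idx((size_t)Ho * Wo * C);
  const double* xp = x.begin();
  for (int c = 0; c < C; ++c) {
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        double best = R_NegInf;
        int besti = -1;
        for (int j = 0; j < k; ++j) {
          int xw = wo * stride - pad + j;
          if (xw < 0 || xw >= W) continue;
          for (int i = 0; i < k; ++i) {
            int xh = ho * stride - pad + i;
            if (xh < 0 || xh >= H) continue;
            size_t fi = xh + (size_t)H * (xw + (size_t)W * c);
            if (xp[fi] > best) { best = xp[fi]; besti = (int)fi; }
          }
        }
        size_t oi = ho + (size_t)Ho * (wo + (size_t)Wo * c);
        y[oi] = (besti < 0) ? 0.0 : best;
        idx[oi] = besti;
      }
    }
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, C);
  idx.attr("dim") = IntegerVector::create(Ho, Wo, C);
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bwd(IntegerVector idx, NumericVector gy,
                              IntegerVector xdim) {
  size_t n = (size_t)xdim[0] * xdim[1] * xdim[2];
  NumericVector gx(n);
  std::fill(gx.begin(), gx.end(), 0.0);
  for (R_xlen_t i = 0; i < gy.size(); ++i)
    if (idx[i] >= 0) gx[idx[i]] += gy[i];
  gx.attr("dim") = xdim;
  return gx;
}

// ---------------------------------------------------------------------------
// RoIAlign (aligned variant: half-pixel offset, no coordinate quantization)
// ---------------------------------------------------------------------------

struct BiLin {
  int y0, x0, y1, x1;
  double w00, w01, w10, w11;
  bool ok;
};

static inline BiLin bilin_prep(double y, double x, int H, int W) {
  BiLin b;
  if (y < -1.0 || y > (double)H || x < -1.0 || x > (double)W) {
    b.ok = false;
    return b;
  }
  b.ok = true;
  if (y < 0) y = 0;
  if (x < 0) x = 0;
  b.y0 = (int)y;
  b.x0 = (int)x;
  if (b.y0 >= H - 1) { b.y0 = b.y1 = H - 1; y = (double)b.y0; } else b.y1 = b.y0 + 1;
  if (b.x0 >= W - 1) { b.x0 = b.x1 = W - 1; x = (double)b.x0; } else b.x1 = b.x0 + 1;
  double ly = y - b.y0, lx = x - b.x0;
  b.w00 = (1 - ly) * (1 - lx);
  b.w01 = (1 - ly) * lx;
  b.w10 = ly * (1 - lx);
  b.w11 = ly * lx;
  return b;
}

// [[Rcpp::export]]
NumericVector cpp_roialign_fwd(NumericVector feat, NumericMatrix rois,
                               double scale, int oh, int ow, int sampling) {
  IntegerVector fd = feat.attr("dim");
  int H = fd[0], W = fd[1], C = fd[2];
  int n = rois.nrow();
  NumericVector out((size_t)oh * ow * C * n);
  std::fill(out.begin(), out.end(), 0.0);
  const double* fp = feat.begin();
  for (int r = 0; r < n; ++r) {
    double x1 = rois(r, 0) * scale - 0.5;
    double y1 = rois(r, 1) * scale - 0.5;
    double x2 = rois(r, 2) * scale - 0.5;
    double y2 = rois(r, 3) * scale - 0.5;
    double rw = std::max(x2 - x1, 1e-6), rh = std::max(y2 - y1, 1e-6);
    double bw = rw / ow, bh = rh / oh;
    int gy = sampling > 0 ? sampling : std::max(1, (int)std::ceil(rh / oh));
    int gx = sampling > 0 ? sampling : std::max(1, (int)std::ceil(rw / ow));
    double inv = 1.0 / (gy * gx);
    for (int pw = 0; pw < ow; ++pw) {
      for (int ph = 0; ph < oh; ++ph) {
        for (int iy = 0; iy < gy; ++iy) {
          double yy = y1 + ph * bh + (iy + 0.5) * bh / gy;
          for (int ix = 0; ix < gx; ++ix) {
            double xx = x1 + pw * bw + (ix + 0.5) * bw / gx;
            BiLin b = bilin_prep(yy, xx, H, W);
            if (!b.ok) continue;
            for (int c = 0; c < C; ++c) {
              const double* fc = fp + (size_t)H * W * c;
              double v = b.w00 * fc[b.y0 + (size_t)H * b.x0] +
                         b.w01 * fc[b.y0 + (size_t)H * b.x1] +
                         b.w10 * fc[b.y1 + (size_t)H * b.x0] +
                         b.w11 * fc[b.y1 + (size_t)H * b.x1];
              out[ph + (size_t)oh * (pw + (size_t)ow * (c + (size_t)C * r))] +=
                  v * inv;
            }
          }
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(oh, ow, C, n);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_roialign_bwd(NumericVector gy_, NumericMatrix rois,
                               double scale, int H, int W, int C, int oh,
                               int ow, int sampling) {
  int n = rois.nrow();
  NumericVector gf((size_t)H * W * C);
  std::fill(gf.begin(), gf.end(), 0.0);
  double* gp = gf.begin();
  const double* gyp = gy_.begin();
  for (int r = 0; r < n; ++r) {
    double x1 = rois(r, 0) * scale - 0.5;
    double y1 = rois(r, 1) * scale - 0.5;
    double x2 = rois(r, 2) * scale - 0.5;
    double y2 = rois(r, 3) * scale - 0.5;
    double rw = std::max(x2 - x1, 1e-6), rh = std::max(y2 - y1, 1e-6);
    double bw = rw / ow, bh = rh / oh;
    int gyn = sampling > 0 ? sampling : std::max(1, (int)std::ceil(rh / oh));
    int gxn = sampling > 0 ? sampling : std::max(1, (int)std::ceil(rw / ow));
    double inv = 1.0 / (gyn * gxn);
    for (int pw = 0; pw < ow; ++pw) {
      for (int ph = 0; ph < oh; ++ph) {
        for (int iy = 0; iy < gyn; ++iy) {
          double yy = y1 + ph * bh + (iy + 0.5) * bh / gyn;
          for (int ix = 0; ix < gxn; ++ix) {
            double xx = x1 + pw * bw + (ix + 0.5) * bw / gxn;
            BiLin b = bilin_prep(yy, xx, H, W);
            if (!b.ok) continue;
            for (int c = 0; c < C; ++c) {
              double g =
                  gyp[ph + (size_t)oh * (pw + (size_t)ow * (c + (size_t)C * r))] *
                  inv;
              double* fc = gp + (size_t)H * W * c;
              fc[b.y0 + (size_t)H * b.x0] += g * b.w00;
              fc[b.y0 + (size_t)H * b.x1] += g * b.w01;
              fc[b.y1 + (size_t)H * b.x0] += g * b.w10;
              fc[b.y1 + (size_t)H * b.x1] += g * b.w11;
            }
          }
        }
      }
    }
  }
  gf.attr("dim") = IntegerVector::create(H, W, C);
  return gf;
}

// ---------------------------------------------------------------------------
// polygon rasterization: even-odd scanline sampled at pixel centers
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerMatrix cpp_fill_polygon(NumericMatrix pts, int h, int w) {
  IntegerMatrix m(h, w);
  int np = pts.nrow();
  if (np < 3) return m;
  std::vector<double> xs;
  xs.reserve(16);
  for (int r = 0; r < h; ++r) {
    double y = r + 0.5;
    xs.clear();
    for (int i = 0; i < np; ++i) {
      int j = (i + 1) % np;
      double y1 = pts(i, 1), y2 = pts(j, 1);
      if ((y1 <= y) == (y2 <= y)) continue;
      double x1 = pts(i, 0), x2 = pts(j, 0);
      xs.push_back(x1 + (y - y1) * (x2 - x1) / (y2 - y1));
    }
    std::sort(xs.begin(), xs.end());
    for (size_t k = 0; k + 1 < xs.size(); k += 2) {
      int c0 = (int)std::ceil(xs[k] - 0.5);
      int c1 = (int)std::ceil(xs[k + 1] - 0.5) - 1;
      if (c0 < 0) c0 = 0;
      if (c1 >= w) c1 = w - 1;
      for (int c = c0; c <= c1; ++c) m(r, c) = 1;
    }
  }
  return m;
}

// ---------------------------------------------------------------------------
// binary image utilities (4-connectivity throughout)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerMatrix cpp_label4(IntegerMatrix mask) {
  int h = mask.nrow(), w = mask.ncol();
  IntegerMatrix lab(h, w);
  std::vector<int> stack;
  int next = 0;
  for (int c = 0; c < w; ++c) {
    for (int r = 0; r < h; ++r) {
      if (!mask(r, c) || lab(r, c)) continue;
      ++next;
      stack.clear();
      stack.push_back(r + h * c);
      lab(r, c) = next;
      while (!stack.empty()) {
        int p = stack.back();
        stack.pop_back();
        int pr = p % h, pc = p / h;
        const int dr[4] = {-1, 1, 0, 0};
        const int dc[4] = {0, 0, -1, 1};
        for (int k = 0; k < 4; ++k) {
          int nr = pr + dr[k], nc = pc + dc[k];
          if (nr < 0 || nr >= h || nc < 0 || nc >= w) continue;
          if (mask(nr, nc) && !lab(nr, nc)) {
            lab(nr, nc) = next;
            stack.push_back(nr + h * nc);
          }
        }
      }
    }
  }
  return lab;
}

// [[Rcpp::export]]
IntegerMatrix cpp_fill_holes4(IntegerMatrix mask) {
  int h = mask.nrow(), w = mask.ncol();
  IntegerMatrix open(h, w);  // background reachable from the border
  std::vector<int> stack;
  for (int c = 0; c < w; ++c) {
    for (int r = 0; r < h; ++r) {
      if (r != 0 && r != h - 1 && c != 0 && c != w - 1) continue;
      if (mask(r, c) || open(r, c)) continue;
      open(r, c) = 1;
      stack.push_back(r + h * c);
      while (!stack.empty()) {
        int p = stack.back();
        stack.pop_back();
        int pr = p % h, pc = p / h;
        const int dr[4] = {-1, 1, 0, 0};
        const int dc[4] = {0, 0, -1, 1};
        for (int k = 0; k < 4; ++k) {
          int nr = pr + dr[k], nc = pc + dc[k];
          if (nr < 0 || nr >= h || nc < 0 || nc >= w) continue;
          if (!mask(nr, nc) && !open(nr, nc)) {
            open(nr, nc) = 1;
            stack.push_back(nr + h * nc);
          }
        }
      }
    }
  }
  IntegerMatrix out(h, w);
  for (int c = 0; c < w; ++c)
    for (int r = 0; r < h; ++r) out(r, c) = (mask(r, c) || !open(r, c)) ? 1 : 0;
  return out;
}

// ---------------------------------------------------------------------------
// boundary tracing: closed loops of pixel-corner vertices, clockwise in
// screen coordinates, interior kept on the right; at pinch vertices the walk
// takes the sharpest right turn so loops stay simple and disjoint.
// ---------------------------------------------------------------------------

static inline bool edge_exists(const IntegerMatrix& m, int h, int w, int x,
                               int y, int d) {
  // d: 0 = +x, 1 = +y, 2 = -x, 3 = -y, from vertex (x, y)
  auto in = [&](int r, int c) {
    return r >= 0 && r < h && c >= 0 && c < w && m(r, c) != 0;
  };
  switch (d) {
    case 0: return in(y, x) && !in(y - 1, x);          // top edge of (y, x)
    case 1: return in(y, x - 1) && !in(y, x);          // right edge of (y, x-1)
    case 2: return in(y - 1, x - 1) && !in(y, x - 1);  // bottom edge
    case 3: return in(y - 1, x) && !in(y - 1, x - 1);  // left edge
  }
  return false;
}

// [[Rcpp::export]]
List cpp_trace_boundaries(IntegerMatrix mask) {
  int h = mask.nrow(), w = mask.ncol();
  const int dx[4] = {1, 0, -1, 0};
  const int dy[4] = {0, 1, 0, -1};
  int vw = w + 1;
  std::vector<std::vector<bool>> used(
      4, std::vector<bool>((size_t)(h + 1) * vw, false));
  List loops;
  for (int y0 = 0; y0 <= h; ++y0) {
    for (int x0 = 0; x0 <= w; ++x0) {
      for (int d0 = 0; d0 < 4; ++d0) {
        if (!edge_exists(mask, h, w, x0, y0, d0)) continue;
        if (used[d0][y0 * vw + x0]) continue;
        std::vector<double> vx, vy;
        int x = x0, y = y0, d = d0;
        for (;;) {
          used[d][y * vw + x] = true;
          int nx = x + dx[d], ny = y + dy[d];
          // choose next direction: right turn, straight, then left turn
          int cand[3] = {(d + 1) % 4, d, (d + 3) % 4};
          int nd = -1;
          for (int k = 0; k < 3; ++k)
            if (edge_exists(mask, h, w, nx, ny, cand[k])) { nd = cand[k]; break; }
          if (nd < 0) stop("boundary trace: dead end (malformed mask)");
          if (nd != d) {  // direction changes: nx,ny is a polygon vertex
            vx.push_back(nx);
            vy.push_back(ny);
          }
          x = nx; y = ny; d = nd;
          if (x == x0 && y == y0 && d == d0) break;
        }
        NumericMatrix poly(vx.size(), 2);
        for (size_t i = 0; i < vx.size(); ++i) {
          poly(i, 0) = vx[i];
          poly(i, 1) = vy[i];
        }
        loops.push_back(poly);
      }
    }
  }
  return loops;
}

// ---------------------------------------------------------------------------
// bilinear image resize (half-pixel centers, clamped)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericMatrix cpp_bilinear_resize(NumericMatrix m, int oh, int ow) {
  int h = m.nrow(), w = m.ncol();
  NumericMatrix out(oh, ow);
  double sy = (double)h / oh, sx = (double)w / ow;
  for (int c = 0; c < ow; ++c) {
    double x = (c + 0.5) * sx - 0.5;
    if (x < 0) x = 0;
    if (x > w - 1) x = w - 1;
    int x0 = (int)x, x1 = std::min(x0 + 1, w - 1);
    double lx = x - x0;
    for (int r = 0; r < oh; ++r) {
      double y = (r + 0.5) * sy - 0.5;
      if (y < 0) y = 0;
      if (y > h - 1) y = h - 1;
      int y0 = (int)y, y1 = std::min(y0 + 1, h - 1);
      double ly = y - y0;
      out(r, c) = (1 - ly) * ((1 - lx) * m(y0, x0) + lx * m(y0, x1)) +
                  ly * ((1 - lx) * m(y1, x0) + lx * m(y1, x1));
    }
  }
  return out;
}
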