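// Low-level numerical kernels: separable Gaussian smoothing (reflective
// boundary), im2col/GEMM 2-D convolutions with backprop, nearest-neighbour
// 2x upsampling, bilinear/nearest warping under a dense displacement field
// (with the spatial-transformer gradient w.r.t. the field), and raster
// resizing (area-average for downscale, bilinear for upscale).
//
// Image layout everywhere: column-major R arrays dim (H, W) or (H, W, C);
// row index = y, column index = x. Displacement fields are (H, W) matrices
// dx (offset along x/columns) and dy (offset along y/rows); output pixel
// (y, x) samples the input at (y + dy, x + dx), clamped to the border.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int reflect_index(int i, int n) {
  // scipy-style "reflect": (d c b a | a b c d | d c b a)
  if (n == 1) return 0;
  const int period = 2 * n;
  i %= period;
  if (i < 0) i += period;
  return (i < n) ? i : (period - 1 - i);
}

// [[Rcpp::export]]
NumericMatrix cpp_sepgauss(NumericMatrix x, double sigma, int fsize) {
  const int H = x.nrow(), W = x.ncol();
  const int half = fsize / 2;
  std::vector<double> g(fsize);
  double s = 0.0;
  for (int i = 0; i < fsize; ++i) {
    const double d = i - half;
    g[i] = std::exp(-0.5 * d * d / (sigma * sigma));
    s += g[i];
  }
  for (int i = 0; i < fsize; ++i) g[i] /= s;

  NumericMatrix tmp(H, W), out(H, W);
  // vertical pass
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      double acc = 0.0;
      for (int t = 0; t < fsize; ++t)
        acc += g[t] * x(reflect_index(r + t - half, H), c);
      tmp(r, c) = acc;
    }
  }
  // horizontal pass
  for (int r = 0; r < H; ++r) {
    for (int c = 0; c < W; ++c) {
      double acc = 0.0;
      for (int t = 0; t < fsize; ++t)
        acc += g[t] * tmp(r, reflect_index(c + t - half, W));
      out(r, c) = acc;
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// im2col convolution, zero padding "same", odd kernel, stride 1 or 2.
// Weights are (k, k, Cin, Cout); column rows are ordered (ki, kj, ci) with
// ki fastest, matching the flattened weight layout.
// ---------------------------------------------------------------------------

// Pixel-major im2col: col is (Npix x k*k*Cin) with column index
// q = ki + k*kj + k*k*ci, matching the flattened (k, k, Cin, Cout) weight
// layout, so y = col * W gives the (Ho, Wo, Cout) output array directly.
// The stride-1 path copies whole (possibly truncated) image columns.
// Scratch buffers reused across calls: the column matrices at full
// resolution are large (tens of MB), and repeated allocation would be
// dominated by page faulting rather than arithmetic.
static std::vector<double>& scratch_buffer(int which, size_t n) {
  static std::vector<double> buf[2];
  if (buf[which].size() < n) buf[which].resize(n);
  return buf[which];
}

static arma::mat im2col_pm(const double* x, int H, int W, int Cin,
                           int k, int stride, int Ho, int Wo) {
  const int pad = (k - 1) / 2;
  const size_t npix = (size_t)Ho * Wo;
  arma::mat col(scratch_buffer(0, npix * k * k * Cin).data(),
                npix, (size_t)k * k * Cin, false, true);
  for (int ci = 0; ci < Cin; ++ci) {
    const double* plane = x + (size_t)ci * H * W;
    for (int kj = 0; kj < k; ++kj) {
      const int dxo = kj - pad;
      for (int ki = 0; ki < k; ++ki) {
        const int dyo = ki - pad;
        double* dst = col.colptr((size_t)ki + k * kj + (size_t)k * k * ci);
        if (stride == 1) {
          for (int wo = 0; wo < Wo; ++wo) {
            double* d = dst + (size_t)H * wo;
            const int xx = wo + dxo;
            if (xx < 0 || xx >= W) { std::fill(d, d + H, 0.0); continue; }
            const double* s = plane + (size_t)H * xx;
            const int lo = std::max(0, -dyo), hi = std::min(H, H - dyo);
            for (int r = 0; r < lo; ++r) d[r] = 0.0;
            if (hi > lo) std::memcpy(d + lo, s + lo + dyo,
                                     (size_t)(hi - lo) * sizeof(double));
            for (int r = hi; r < H; ++r) d[r] = 0.0;
          }
        } else {
          for (int wo = 0; wo < Wo; ++wo) {
            double* d = dst + (size_t)Ho * wo;
            const int xx = wo * stride + dxo;
            if (xx < 0 || xx >= W) { std::fill(d, d + Ho, 0.0); continue; }
            const double* s = plane + (size_t)H * xx;
            for (int ho = 0; ho < Ho; ++ho) {
              const int yy = ho * stride + dyo;
              d[ho] = (yy >= 0 && yy < H) ? s[yy] : 0.0;
            }
          }
        }
      }
    }
  }
  return col;
}

// Extract the (Cin x Cout) weight slice for kernel offset (ki, kj).
static arma::mat weight_slice(const double* w, int k, int Cin, int Cout,
                              int ki, int kj) {
  arma::mat Wq(Cin, Cout);
  for (int co = 0; co < Cout; ++co)
    for (int ci = 0; ci < Cin; ++ci)
      Wq(ci, co) = w[ki + k * kj + (size_t)k * k * ci +
                     (size_t)k * k * Cin * co];
  return Wq;
}

// Rows of the output that were fed by a column-wrapped source pixel when
// treating the kernel offset as a constant linear-index shift. For
// dyo = -1 these are the first row of each image column; for dyo = +1 the
// last row. Their true zero-padded contribution is subtracted afterwards.
static inline void wrapped_rows(int H, int W, int dyo, int dxo,
                                std::vector<int>& rows) {
  rows.clear();
  if (dyo == 0) return;
  // every output row whose vertical source index leaves [0, H); whether a
  // given row actually entered the GEMM is decided by the caller's
  // [r0, r1) range check, so all image columns are enumerated here
  const int yr = (dyo < 0) ? 0 : H - 1;
  for (int xc = 0; xc < W; ++xc) rows.push_back(yr + H * xc);
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_forward(NumericVector x, NumericVector w,
                                 NumericVector b, int stride) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Cin = (xd.size() > 2) ? xd[2] : 1;
  const int k = wd[0], Cout = wd[3];
  const int Ho = (H + stride - 1) / stride, Wo = (W + stride - 1) / stride;
  const size_t npix = (size_t)Ho * Wo;

  NumericVector out(npix * Cout);
  out.attr("dim") = IntegerVector::create(Ho, Wo, Cout);
  arma::mat Y(out.begin(), npix, Cout, false, true);

  if (stride == 1) {
    // shift-GEMM: for each kernel offset, one GEMM on a constant-offset
    // row range of the raw (Npix x Cin) image view, then border fixes
    const int pad = (k - 1) / 2;
    arma::mat X(const_cast<double*>(x.begin()), npix, Cin, false, true);
    std::vector<int> wr;
    for (int kj = 0; kj < k; ++kj) {
      const int dxo = kj - pad;
      for (int ki = 0; ki < k; ++ki) {
        const int dyo = ki - pad;
        const long off = dyo + (long)H * dxo;
        const long r0 = std::max(0L, -off);
        const long r1 = (long)npix - std::max(0L, off);
        if (r1 <= r0) continue;
        arma::mat Wq = weight_slice(w.begin(), k, Cin, Cout, ki, kj);
        Y.rows(r0, r1 - 1) += X.rows(r0 + off, r1 - 1 + off) * Wq;
        wrapped_rows(H, W, dyo, dxo, wr);
        for (int r : wr) {
          if (r < r0 || r >= r1) continue;
          const long s = r + off;
          for (int co = 0; co < Cout; ++co) {
            double acc = 0.0;
            for (int ci = 0; ci < Cin; ++ci) acc += X(s, ci) * Wq(ci, co);
            Y(r, co) -= acc;
          }
        }
      }
    }
  } else {
    arma::mat col = im2col_pm(x.begin(), H, W, Cin, k, stride, Ho, Wo);
    arma::mat Wm(const_cast<double*>(w.begin()), (size_t)k * k * Cin, Cout,
                 false, true);
    Y = col * Wm;
  }
  for (int co = 0; co < Cout; ++co) Y.col(co) += b[co];
  return out;
}

// [[Rcpp::export]]
List cpp_conv2d_backward(NumericVector x, NumericVector w, NumericVector dy,
                         int stride) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), yd = dy.attr("dim");
  const int H = xd[0], W = xd[1], Cin = (xd.size() > 2) ? xd[2] : 1;
  const int k = wd[0], Cout = wd[3];
  const int Ho = yd[0], Wo = yd[1];
  const int pad = (k - 1) / 2;
  const size_t npix = (size_t)Ho * Wo;

  arma::mat dY(const_cast<double*>(dy.begin()), npix, Cout, false, true);

  NumericVector dw(w.size());
  dw.attr("dim") = wd;
  NumericVector db(Cout);
  for (int co = 0; co < Cout; ++co) db[co] = arma::accu(dY.col(co));

  NumericVector dx((size_t)H * W * Cin);
  dx.attr("dim") = IntegerVector::create(H, W, Cin);

  if (stride == 1) {
    arma::mat X(const_cast<double*>(x.begin()), npix, Cin, false, true);
    arma::mat dX(dx.begin(), npix, Cin, false, true);
    std::vector<int> wr;
    for (int kj = 0; kj < k; ++kj) {
      const int dxo = kj - pad;
      for (int ki = 0; ki < k; ++ki) {
        const int dyo = ki - pad;
        const long off = dyo + (long)H * dxo;
        const long r0 = std::max(0L, -off);
        const long r1 = (long)npix - std::max(0L, off);
        if (r1 <= r0) continue;
        wrapped_rows(H, W, dyo, dxo, wr);

        // dW slice = X_shift^T dY (minus wrongly included wrapped rows)
        arma::mat dWq = X.rows(r0 + off, r1 - 1 + off).t() *
                        dY.rows(r0, r1 - 1);
        for (int r : wr) {
          if (r < r0 || r >= r1) continue;
          const long s = r + off;
          for (int co = 0; co < Cout; ++co)
            for (int ci = 0; ci < Cin; ++ci)
              dWq(ci, co) -= X(s, ci) * dY(r, co);
        }
        for (int co = 0; co < Cout; ++co)
          for (int ci = 0; ci < Cin; ++ci)
            dw[ki + k * kj + (size_t)k * k * ci +
               (size_t)k * k * Cin * co] = dWq(ci, co);

        // dX_shift += dY Wq^T (then undo the wrapped rows)
        arma::mat Wq = weight_slice(w.begin(), k, Cin, Cout, ki, kj);
        dX.rows(r0 + off, r1 - 1 + off) += dY.rows(r0, r1 - 1) * Wq.t();
        for (int r : wr) {
          if (r < r0 || r >= r1) continue;
          const long s = r + off;
          for (int ci = 0; ci < Cin; ++ci) {
            double acc = 0.0;
            for (int co = 0; co < Cout; ++co) acc += dY(r, co) * Wq(ci, co);
            dX(s, ci) -= acc;
          }
        }
      }
    }
  } else {
    arma::mat col = im2col_pm(x.begin(), H, W, Cin, k, stride, Ho, Wo);
    arma::mat Wm(const_cast<double*>(w.begin()), (size_t)k * k * Cin, Cout,
                 false, true);
    arma::mat dWm(dw.begin(), (size_t)k * k * Cin, Cout, false, true);
    dWm = col.t() * dY;
    arma::mat dcol(scratch_buffer(1, npix * k * k * Cin).data(),
                   npix, (size_t)k * k * Cin, false, true);
    dcol = dY * Wm.t();  // Npix x k*k*Cin
    double* dxp = dx.begin();
    for (int ci = 0; ci < Cin; ++ci) {
      double* plane = dxp + (size_t)ci * H * W;
      for (int kj = 0; kj < k; ++kj) {
        const int dxo = kj - pad;
        for (int ki = 0; ki < k; ++ki) {
          const int dyo = ki - pad;
          const double* src =
            dcol.colptr((size_t)ki + k * kj + (size_t)k * k * ci);
          for (int wo = 0; wo < Wo; ++wo) {
            const int xx = wo * stride + dxo;
            if (xx < 0 || xx >= W) continue;
            double* d = plane + (size_t)H * xx;
            const double* s = src + (size_t)Ho * wo;
            for (int ho = 0; ho < Ho; ++ho) {
              const int yy = ho * stride + dyo;
              if (yy >= 0 && yy < H) d[yy] += s[ho];
            }
          }
        }
      }
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// [[Rcpp::export]]
NumericVector cpp_upsample2(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = (xd.size() > 2) ? xd[2] : 1;
  NumericVector out((size_t)4 * H * W * C);
  out.attr("dim") = IntegerVector::create(2 * H, 2 * W, C);
  const double* xp = x.begin();
  double* op = out.begin();
  for (int c = 0; c < C; ++c)
    for (int wo = 0; wo < 2 * W; ++wo)
      for (int ho = 0; ho < 2 * H; ++ho)
        op[(size_t)ho + (size_t)2 * H * wo + (size_t)4 * H * W * c] =
          xp[(size_t)(ho / 2) + (size_t)H * (wo / 2) + (size_t)H * W * c];
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_upsample2_backward(NumericVector dy) {
  IntegerVector yd = dy.attr("dim");
  const int H2 = yd[0], W2 = yd[1], C = (yd.size() > 2) ? yd[2] : 1;
  const int H = H2 / 2, W = W2 / 2;
  NumericVector out((size_t)H * W * C);
  out.attr("dim") = IntegerVector::create(H, W, C);
  const double* dp = dy.begin();
  double* op = out.begin();
  for (int c = 0; c < C; ++c)
    for (int wo = 0; wo < W2; ++wo)
      for (int ho = 0; ho < H2; ++ho)
        op[(size_t)(ho / 2) + (size_t)H * (wo / 2) + (size_t)H * W * c] +=
          dp[(size_t)ho + (size_t)H2 * wo + (size_t)H2 * W2 * c];
  return out;
}

// ---------------------------------------------------------------------------
// Warping under a dense displacement field; out-of-bounds samples clamp.
// ---------------------------------------------------------------------------

static inline double clampd(double v, double lo, double hi) {
  return (v < lo) ? lo : ((v > hi) ? hi : v);
}

// [[Rcpp::export]]
NumericVector cpp_warp_bilinear(NumericVector img, NumericMatrix dx,
                                NumericMatrix dy) {
  IntegerVector id = img.attr("dim");
  const int H = id[0], W = id[1], C = (id.size() > 2) ? id[2] : 1;
  NumericVector out(img.size());
  out.attr("dim") = id;
  const double* ip = img.begin();
  double* op = out.begin();
  for (int x = 0; x < W; ++x) {
    for (int y = 0; y < H; ++y) {
      const double sx = clampd(x + dx(y, x), 0.0, W - 1.0);
      const double sy = clampd(y + dy(y, x), 0.0, H - 1.0);
      const int x0 = (int)std::floor(sx), y0 = (int)std::floor(sy);
      const int x1 = std::min(x0 + 1, W - 1), y1 = std::min(y0 + 1, H - 1);
      const double wx = sx - x0, wy = sy - y0;
      for (int c = 0; c < C; ++c) {
        const double* pc = ip + (size_t)c * H * W;
        const double v =
          (1 - wy) * ((1 - wx) * pc[y0 + (size_t)H * x0] +
                      wx * pc[y0 + (size_t)H * x1]) +
          wy * ((1 - wx) * pc[y1 + (size_t)H * x0] +
                wx * pc[y1 + (size_t)H * x1]);
        op[(size_t)y + (size_t)H * x + (size_t)c * H * W] = v;
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_warp_nearest(NumericVector img, NumericMatrix dx,
                               NumericMatrix dy) {
  IntegerVector id = img.attr("dim");
  const int H = id[0], W = id[1], C = (id.size() > 2) ? id[2] : 1;
  NumericVector out(img.size());
  out.attr("dim") = id;
  const double* ip = img.begin();
  double* op = out.begin();
  for (int x = 0; x < W; ++x) {
    for (int y = 0; y < H; ++y) {
      const int sx = (int)clampd(std::round(x + dx(y, x)), 0.0, W - 1.0);
      const int sy = (int)clampd(std::round(y + dy(y, x)), 0.0, H - 1.0);
      for (int c = 0; c < C; ++c)
        op[(size_t)y + (size_t)H * x + (size_t)c * H * W] =
          ip[(size_t)sy + (size_t)H * sx + (size_t)c * H * W];
    }
  }
  return out;
}

// Gradient of sum(dout * warp_bilinear(img, dx, dy)) w.r.t. dx and dy.
// At clamped samples the derivative is zero (the sample no longer moves
// with the field), which the (x1 - x0) collapse below produces naturally.
// [[Rcpp::export]]
List cpp_warp_backward(NumericVector img, NumericMatrix dx, NumericMatrix dy,
                       NumericVector dout) {
  IntegerVector id = img.attr("dim");
  const int H = id[0], W = id[1], C = (id.size() > 2) ? id[2] : 1;
  NumericMatrix gdx(H, W), gdy(H, W);
  const double* ip = img.begin();
  const double* gp = dout.begin();
  for (int x = 0; x < W; ++x) {
    for (int y = 0; y < H; ++y) {
      const double rx = x + dx(y, x), ry = y + dy(y, x);
      const bool in_x = (rx > 0.0 && rx < W - 1.0);
      const bool in_y = (ry > 0.0 && ry < H - 1.0);
      const double sx = clampd(rx, 0.0, W - 1.0);
      const double sy = clampd(ry, 0.0, H - 1.0);
      const int x0 = (int)std::floor(sx), y0 = (int)std::floor(sy);
      const int x1 = std::min(x0 + 1, W - 1), y1 = std::min(y0 + 1, H - 1);
      const double wx = sx - x0, wy = sy - y0;
      double ax = 0.0, ay = 0.0;
      for (int c = 0; c < C; ++c) {
        const double* pc = ip + (size_t)c * H * W;
        const double i00 = pc[y0 + (size_t)H * x0], i01 = pc[y0 + (size_t)H * x1];
        const double i10 = pc[y1 + (size_t)H * x0], i11 = pc[y1 + (size_t)H * x1];
        const double g = gp[(size_t)y + (size_t)H * x + (size_t)c * H * W];
        if (in_x) ax += g * ((1 - wy) * (i01 - i00) + wy * (i11 - i10));
        if (in_y) ay += g * ((1 - wx) * (i10 - i00) + wx * (i11 - i01));
      }
      gdx(y, x) = ax;
      gdy(y, x) = ay;
    }
  }
  return List::create(_["ddx"] = gdx, _["ddy"] = gdy);
}

// ---------------------------------------------------------------------------
// Resizing (single channel; channels handled in R).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericMatrix cpp_resize_bilinear(NumericMatrix x, int Ho, int Wo) {
  const int H = x.nrow(), W = x.ncol();
  NumericMatrix out(Ho, Wo);
  const double fy = (double)H / Ho, fx = (double)W / Wo;
  for (int xo = 0; xo < Wo; ++xo) {
    const double sx = clampd((xo + 0.5) * fx - 0.5, 0.0, W - 1.0);
    const int x0 = (int)std::floor(sx), x1 = std::min(x0 + 1, W - 1);
    const double wx = sx - x0;
    for (int yo = 0; yo < Ho; ++yo) {
      const double sy = clampd((yo + 0.5) * fy - 0.5, 0.0, H - 1.0);
      const int y0 = (int)std::floor(sy), y1 = std::min(y0 + 1, H - 1);
      const double wy = sy - y0;
      out(yo, xo) = (1 - wy) * ((1 - wx) * x(y0, x0) + wx * x(y0, x1)) +
                    wy * ((1 - wx) * x(y1, x0) + wx * x(y1, x1));
    }
  }
  return out;
}

// Coverage-weighted area average (anti-aliased downscale; exact block mean
// for integer decimation factors).
// [[Rcpp::export]]
NumericMatrix cpp_resize_area(NumericMatrix x, int Ho, int Wo) {
  const int H = x.nrow(), W = x.ncol();
  NumericMatrix out(Ho, Wo);
  const double fy = (double)H / Ho, fx = (double)W / Wo;
  for (int xo = 0; xo < Wo; ++xo) {
    const double xa = xo * fx, xb = (xo + 1) * fx;
    const int cx0 = (int)std::floor(xa), cx1 = std::min((int)std::ceil(xb), W);
    for (int yo = 0; yo < Ho; ++yo) {
      const double ya = yo * fy, yb = (yo + 1) * fy;
      const int cy0 = (int)std::floor(ya), cy1 = std::min((int)std::ceil(yb), H);
      double acc = 0.0, wsum = 0.0;
      for (int cx = cx0; cx < cx1; ++cx) {
        const double wxx = std::min((double)cx + 1, xb) - std::max((double)cx, xa);
        for (int cy = cy0; cy < cy1; ++cy) {
          const double wyy = std::min((double)cy + 1, yb) - std::max((double)cy, ya);
          acc += wxx * wyy * x(cy, cx);
          wsum += wxx * wyy;
        }
      }
      out(yo, xo) = acc / wsum;
    }
  }
  return out;
}

// Gaussian soft-binning (Parzen) weights: n x bins, rows sum to 1.
// Bin centres at (j - 0.5) / bins; numerically stabilised per row.
// [[Rcpp::export]]
NumericMatrix cpp_parzen_weights(NumericVector v, int bins, double bw) {
  const int n = v.size();
  NumericMatrix out(n, bins);
  const double inv2 = 0.5 / (bw * bw);
  std::vector<double> cen(bins);
  for (int j = 0; j < bins; ++j) cen[j] = (j + 0.5) / bins;
  for (int i = 0; i < n; ++i) {
    const double vi = v[i];
    double mx = -1e300;
    for (int j = 0; j < bins; ++j) {
      const double d = vi - cen[j];
      const double e = -d * d * inv2;
      out(i, j) = e;
      if (e > mx) mx = e;
    }
    double s = 0.0;
    for (int j = 0; j < bins; ++j) {
      const double w = std::exp(out(i, j) - mx);
      out(i, j) = w;
      s += w;
    }
    for (int j = 0; j < bins; ++j) out(i, j) /= s;
  }
  return out;
}
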