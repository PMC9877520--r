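// Numeric kernels: im2col convolution forward/backward, max pooling with
// argmax bookkeeping, and the fixed-viewpoint surface rasterizer.
//
// Activation tensors are R arrays in (H, W, C, N) column-major layout;
// convolution weights are (kh, kw, C, F). Padding follows the "same"
// convention of the common frameworks: total pad = max((Ho-1)*s + k - H, 0)
// with the smaller half on the top/left, Ho = ceil(H / s).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline void same_pad(int in, int k, int stride, int &out, int &pad_lo) {
  out = (in + stride - 1) / stride;
  int tot = std::max((out - 1) * stride + k - in, 0);
  pad_lo = tot / 2;
}

static inline void valid_out(int in, int k, int stride, int &out) {
  out = (in - k) / stride + 1;
}

// Fill the im2col buffer (kh*kw*C x Ho*Wo) for image n of x.
static void im2col(const double *x, int H, int W, int C, int kh, int kw,
                   int stride, int pad_h, int pad_w, int Ho, int Wo,
                   arma::mat &cols) {
  const int K = kh * kw * C;
  cols.set_size(K, Ho * Wo);
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      double *dst = cols.colptr(ho + Ho * wo);
      int h0 = ho * stride - pad_h;
      int w0 = wo * stride - pad_w;
      int p = 0;
      for (int c = 0; c < C; ++c) {
        const double *xc = x + (size_t)c * H * W;
        for (int dw = 0; dw < kw; ++dw) {
          int wI = w0 + dw;
          for (int dh = 0; dh < kh; ++dh, ++p) {
            int hI = h0 + dh;
            dst[p] = (hI >= 0 && hI < H && wI >= 0 && wI < W)
                         ? xc[hI + (size_t)H * wI]
                         : 0.0;
          }
        }
      }
      (void)K;
    }
  }
}

// Scatter-add the column buffer back into a padded-image gradient.
static void col2im(const arma::mat &cols, double *dx, int H, int W, int C,
                   int kh, int kw, int stride, int pad_h, int pad_w, int Ho,
                   int Wo) {
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const double *src = cols.colptr(ho + Ho * wo);
      int h0 = ho * stride - pad_h;
      int w0 = wo * stride - pad_w;
      int p = 0;
      for (int c = 0; c < C; ++c) {
        double *xc = dx + (size_t)c * H * W;
        for (int dw = 0; dw < kw; ++dw) {
          int wI = w0 + dw;
          for (int dh = 0; dh < kh; ++dh, ++p) {
            int hI = h0 + dh;
            if (hI >= 0 && hI < H && wI >= 0 && wI < W)
              xc[hI + (size_t)H * wI] += src[p];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
List conv_fwd_cpp(NumericVector x, IntegerVector xdim, NumericVector w,
                  IntegerVector wdim, int stride, bool same) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int kh = wdim[0], kw = wdim[1], F = wdim[3];
  if (wdim[2] != C) stop("conv: channel mismatch");
  int Ho, Wo, ph = 0, pw = 0;
  if (same) {
    same_pad(H, kh, stride, Ho, ph);
    same_pad(W, kw, stride, Wo, pw);
  } else {
    valid_out(H, kh, stride, Ho);
    valid_out(W, kw, stride, Wo);
  }
  const int K = kh * kw * C;
  arma::mat Wm(const_cast<double *>(w.begin()), K, F, false, true);
  NumericVector y(Rf_allocVector(REALSXP, (R_xlen_t)Ho * Wo * F * N));
  arma::mat cols;
  for (int n = 0; n < N; ++n) {
    const double *xn = x.begin() + (size_t)n * H * W * C;
    im2col(xn, H, W, C, kh, kw, stride, ph, pw, Ho, Wo, cols);
    // yb (Ho*Wo x F) lands directly in (Ho, Wo, F) layout
    arma::mat yb(y.begin() + (size_t)n * Ho * Wo * F, Ho * Wo, F, false, true);
    yb = cols.t() * Wm;
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, F, N);
  return List::create(_["y"] = y, _["pad"] = IntegerVector::create(ph, pw),
                      _["out"] = IntegerVector::create(Ho, Wo));
}

// [[Rcpp::export]]
List conv_bwd_cpp(NumericVector x, IntegerVector xdim, NumericVector w,
                  IntegerVector wdim, NumericVector dy, int stride,
                  bool same) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int kh = wdim[0], kw = wdim[1], F = wdim[3];
  int Ho, Wo, ph = 0, pw = 0;
  if (same) {
    same_pad(H, kh, stride, Ho, ph);
    same_pad(W, kw, stride, Wo, pw);
  } else {
    valid_out(H, kh, stride, Ho);
    valid_out(W, kw, stride, Wo);
  }
  const int K = kh * kw * C;
  arma::mat Wm(const_cast<double *>(w.begin()), K, F, false, true);
  NumericVector dx(Rf_allocVector(REALSXP, (R_xlen_t)H * W * C * N));
  std::fill(dx.begin(), dx.end(), 0.0);
  NumericVector dw(Rf_allocVector(REALSXP, (R_xlen_t)K * F));
  std::fill(dw.begin(), dw.end(), 0.0);
  arma::mat dWm(dw.begin(), K, F, false, true);
  arma::mat cols, dcols;
  for (int n = 0; n < N; ++n) {
    const double *xn = x.begin() + (size_t)n * H * W * C;
    im2col(xn, H, W, C, kh, kw, stride, ph, pw, Ho, Wo, cols);
    arma::mat dyb(const_cast<double *>(dy.begin()) + (size_t)n * Ho * Wo * F,
                  Ho * Wo, F, false, true);
    dWm += cols * dyb;
    dcols = Wm * dyb.t();
    col2im(dcols, dx.begin() + (size_t)n * H * W * C, H, W, C, kh, kw, stride,
           ph, pw, Ho, Wo);
  }
  dx.attr("dim") = xdim;
  dw.attr("dim") = wdim;
  return List::create(_["dx"] = dx, _["dw"] = dw);
}

// [[Rcpp::export]]
List maxpool_fwd_cpp(NumericVector x, IntegerVector xdim, int k, int stride,
                     bool same) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  int Ho, Wo, ph = 0, pw = 0;
  if (same) {
    same_pad(H, k, stride, Ho, ph);
    same_pad(W, k, stride, Wo, pw);
  } else {
    valid_out(H, k, stride, Ho);
    valid_out(W, k, stride, Wo);
  }
  NumericVector y(Rf_allocVector(REALSXP, (R_xlen_t)Ho * Wo * C * N));
  IntegerVector arg(Rf_allocVector(INTSXP, (R_xlen_t)Ho * Wo * C * N));
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double *xc = x.begin() + (size_t)(n * C + c) * H * W;
      double *yc = y.begin() + (size_t)(n * C + c) * Ho * Wo;
      int *ac = arg.begin() + (size_t)(n * C + c) * Ho * Wo;
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          int h0 = ho * stride - ph, w0 = wo * stride - pw;
          double best = -std::numeric_limits<double>::infinity();
          int bi = -1;
          for (int dw = 0; dw < k; ++dw) {
            int wI = w0 + dw;
            if (wI < 0 || wI >= W) continue;
            for (int dh = 0; dh < k; ++dh) {
              int hI = h0 + dh;
              if (hI < 0 || hI >= H) continue;
              double v = xc[hI + (size_t)H * wI];
              if (v > best) {
                best = v;
                bi = hI + H * wI;
              }
            }
          }
          yc[ho + Ho * wo] = (bi >= 0) ? best : 0.0;
          ac[ho + Ho * wo] = bi;
        }
      }
    }
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  arg.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  return List::create(_["y"] = y, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericVector maxpool_bwd_cpp(NumericVector dy, IntegerVector arg,
                              IntegerVector xdim) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  IntegerVector ydim = arg.attr("dim");
  const int Ho = ydim[0], Wo = ydim[1];
  NumericVector dx(Rf_allocVector(REALSXP, (R_xlen_t)H * W * C * N));
  std::fill(dx.begin(), dx.end(), 0.0);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double *dyc = dy.begin() + (size_t)(n * C + c) * Ho * Wo;
      const int *ac = arg.begin() + (size_t)(n * C + c) * Ho * Wo;
      double *dxc = dx.begin() + (size_t)(n * C + c) * H * W;
      for (int p = 0; p < Ho * Wo; ++p) {
        if (ac[p] >= 0) dxc[ac[p]] += dyc[p];
      }
    }
  }
  dx.attr("dim") = xdim;
  return dx;
}

// Orthographic surface rasterizer. Z is a g x g height field in [-1, 1];
// returns a size x size matrix of surface heights (NA = background), painted
// back-to-front so nearer cells overwrite farther ones.
// [[Rcpp::export]]
NumericMatrix surface_raster_cpp(NumericMatrix Z, int size, double azimuth,
                                 double elevation, double zscale) {
  const int g = Z.nrow();
  if (Z.ncol() != g) stop("surface: height field must be square");
  const double ca = std::cos(azimuth), sa = std::sin(azimuth);
  const double ce = std::cos(elevation), se = std::sin(elevation);

  const int nv = g * g;
  std::vector<double> sx(nv), sy(nv), depth(nv);
  if (g < 2) stop("surface: height field needs >= 2 points per side");
  for (int j = 0; j < g; ++j) {
    for (int i = 0; i < g; ++i) {
      // vertices span the full unit square, so the painted footprint is
      // independent of the grid resolution
      double x = (double)j / (g - 1) - 0.5;
      double y = (double)i / (g - 1) - 0.5;
      double z = Z(i, j) * zscale;
      double x1 = x * ca - y * sa;
      double y1 = x * sa + y * ca;
      int v = i + g * j;
      sx[v] = x1;
      sy[v] = y1 * se + z * ce;
      depth[v] = y1 * ce - z * se;
    }
  }
  // fixed screen bounds: extremes of the rotated unit square at z = +/- zscale
  double r = std::sqrt(0.5);
  double xmin = -r, xmax = r;
  double ymin = -r * se - zscale * ce, ymax = r * se + zscale * ce;
  double mx = 0.05 * (xmax - xmin), my = 0.05 * (ymax - ymin);
  xmin -= mx; xmax += mx; ymin -= my; ymax += my;
  double span = std::max(xmax - xmin, ymax - ymin);
  double xoff = xmin - (span - (xmax - xmin)) / 2;
  double yoff = ymin - (span - (ymax - ymin)) / 2;

  const int nq = (g - 1) * (g - 1);
  std::vector<int> order(nq);
  std::vector<double> qdepth(nq);
  for (int q = 0; q < nq; ++q) {
    int i = q % (g - 1), j = q / (g - 1);
    int v00 = i + g * j, v10 = v00 + 1, v01 = v00 + g, v11 = v01 + 1;
    qdepth[q] = 0.25 * (depth[v00] + depth[v10] + depth[v01] + depth[v11]);
    order[q] = q;
  }
  std::stable_sort(order.begin(), order.end(), [&](int a, int b) {
    return qdepth[a] > qdepth[b]; // farthest first
  });

  NumericMatrix out(size, size);
  std::fill(out.begin(), out.end(), NA_REAL);
  auto px = [&](double v) { return (v - xoff) / span * size; };
  auto py = [&](double v) { return size - (v - yoff) / span * size; };

  for (int qi = 0; qi < nq; ++qi) {
    int q = order[qi];
    int i = q % (g - 1), j = q / (g - 1);
    int vidx[4] = {i + g * j, i + 1 + g * j, i + 1 + g * (j + 1),
                   i + g * (j + 1)};
    double qx[4], qy[4];
    double zmean = 0;
    for (int t = 0; t < 4; ++t) {
      qx[t] = px(sx[vidx[t]]);
      qy[t] = py(sy[vidx[t]]);
    }
    zmean = 0.25 * (Z(i, j) + Z(i + 1, j) + Z(i + 1, j + 1) + Z(i, j + 1));
    double bx0 = std::floor(std::min(std::min(qx[0], qx[1]),
                                     std::min(qx[2], qx[3])));
    double bx1 = std::ceil(std::max(std::max(qx[0], qx[1]),
                                    std::max(qx[2], qx[3])));
    double by0 = std::floor(std::min(std::min(qy[0], qy[1]),
                                     std::min(qy[2], qy[3])));
    double by1 = std::ceil(std::max(std::max(qy[0], qy[1]),
                                    std::max(qy[2], qy[3])));
    for (int cx = std::max(0, (int)bx0); cx < std::min(size, (int)bx1); ++cx) {
      for (int cy = std::max(0, (int)by0); cy < std::min(size, (int)by1);
           ++cy) {
        double ptx = cx + 0.5, pty = cy + 0.5;
        // point-in-quad via winding sign consistency
        bool pos = false, neg = false;
        for (int t = 0; t < 4; ++t) {
          int t2 = (t + 1) % 4;
          double cross = (qx[t2] - qx[t]) * (pty - qy[t]) -
                         (qy[t2] - qy[t]) * (ptx - qx[t]);
          if (cross > 1e-12) pos = true;
          if (cross < -1e-12) neg = true;
        }
        if (!(pos && neg)) {
          // column-major: row = cy, col = cx
          out(cy, cx) = zmean;
        }
      }
    }
  }
  return out;
}
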