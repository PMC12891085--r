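// Low-level array ops for the detector: GEMM-based 2-D convolution with
// groups (forward + backward), max pooling with argmax, nearest-neighbour
// 2x upsampling, and bilinear resize. Tensors are R arrays dim (N, C, H, W),
// column-major, so element (n,c,h,w) sits at n + N*(c + C*(h + H*w)).
#include <RcppArmadillo.h>
using namespace Rcpp;

static inline R_xlen_t idx4(int n, int c, int h, int w,
                            int N, int C, int H) {
  return (R_xlen_t)n + (R_xlen_t)N * ((R_xlen_t)c + (R_xlen_t)C *
         ((R_xlen_t)h + (R_xlen_t)H * (R_xlen_t)w));
}

// im2col for one sample and one channel group.
// col is (Cg*kh*kw) x (Ho*Wo); row = cl*kh*kw + ki*kw + kj, col = oh + Ho*ow.
static void im2col(const double* x, int n, int N, int C, int H, int W,
                   int c0, int Cg, int kh, int kw, int stride, int pad,
                   int Ho, int Wo, arma::mat& col) {
  for (int cl = 0; cl < Cg; ++cl) {
    int c = c0 + cl;
    for (int ki = 0; ki < kh; ++ki) {
      for (int kj = 0; kj < kw; ++kj) {
        int row = cl * kh * kw + ki * kw + kj;
        for (int ow = 0; ow < Wo; ++ow) {
          int w = ow * stride - pad + kj;
          for (int oh = 0; oh < Ho; ++oh) {
            int h = oh * stride - pad + ki;
            double v = 0.0;
            if (h >= 0 && h < H && w >= 0 && w < W)
              v = x[idx4(n, c, h, w, N, C, H)];
            col(row, oh + (R_xlen_t)Ho * ow) = v;
          }
        }
      }
    }
  }
}

static void col2im_add(double* dx, int n, int N, int C, int H, int W,
                       int c0, int Cg, int kh, int kw, int stride, int pad,
                       int Ho, int Wo, const arma::mat& col) {
  for (int cl = 0; cl < Cg; ++cl) {
    int c = c0 + cl;
    for (int ki = 0; ki < kh; ++ki) {
      for (int kj = 0; kj < kw; ++kj) {
        int row = cl * kh * kw + ki * kw + kj;
        for (int ow = 0; ow < Wo; ++ow) {
          int w = ow * stride - pad + kj;
          if (w < 0 || w >= W) continue;
          for (int oh = 0; oh < Ho; ++oh) {
            int h = oh * stride - pad + ki;
            if (h < 0 || h >= H) continue;
            dx[idx4(n, c, h, w, N, C, H)] += col(row, oh + (R_xlen_t)Ho * ow);
          }
        }
      }
    }
  }
}

// Weight array dim (Cout, Cin/g, kh, kw) -> per-group matrix
// (Coutg x Cg*kh*kw), row = local out channel, col = cl*kh*kw + ki*kw + kj.
static arma::mat weight_mat(const double* wt, int g, int Cout, int Cg,
                            int kh, int kw, int Coutg) {
  arma::mat Wm(Coutg, (R_xlen_t)Cg * kh * kw);
  for (int col = 0; col < Coutg; ++col) {
    int co = g * Coutg + col;
    for (int cl = 0; cl < Cg; ++cl)
      for (int ki = 0; ki < kh; ++ki)
        for (int kj = 0; kj < kw; ++kj) {
          R_xlen_t wi = (R_xlen_t)co + (R_xlen_t)Cout *
            ((R_xlen_t)cl + (R_xlen_t)Cg * ((R_xlen_t)ki + (R_xlen_t)kh * kj));
          Wm(col, cl * kh * kw + ki * kw + kj) = wt[wi];
        }
  }
  return Wm;
}

// [[Rcpp::export(name = ".conv2d_fw")]]
NumericVector conv2d_fw(NumericVector x, NumericVector wt,
                        Nullable<NumericVector> bias,
                        int stride, int pad, int groups) {
  IntegerVector xd = x.attr("dim"), wd = wt.attr("dim");
  int N = xd[0], C = xd[1], H = xd[2], W = xd[3];
  int Cout = wd[0], Cg = wd[1], kh = wd[2], kw = wd[3];
  if (C != Cg * groups) stop("channel/group mismatch");
  int Ho = (H + 2 * pad - kh) / stride + 1;
  int Wo = (W + 2 * pad - kw) / stride + 1;
  int Coutg = Cout / groups;
  NumericVector y((R_xlen_t)N * Cout * Ho * Wo);
  y.attr("dim") = IntegerVector::create(N, Cout, Ho, Wo);
  double* yp = y.begin();
  const double* xp = x.begin();
  std::vector<arma::mat> Wms;
  for (int g = 0; g < groups; ++g)
    Wms.push_back(weight_mat(wt.begin(), g, Cout, Cg, kh, kw, Coutg));
  arma::mat col((R_xlen_t)Cg * kh * kw, (R_xlen_t)Ho * Wo);
  for (int n = 0; n < N; ++n) {
    for (int g = 0; g < groups; ++g) {
      im2col(xp, n, N, C, H, W, g * Cg, Cg, kh, kw, stride, pad, Ho, Wo, col);
      arma::mat out = Wms[g] * col;  // Coutg x Ho*Wo
      for (int co = 0; co < Coutg; ++co) {
        int c = g * Coutg + co;
        for (int ow = 0; ow < Wo; ++ow)
          for (int oh = 0; oh < Ho; ++oh)
            yp[idx4(n, c, oh, ow, N, Cout, Ho)] = out(co, oh + (R_xlen_t)Ho * ow);
      }
    }
  }
  if (bias.isNotNull()) {
    NumericVector b(bias);
    for (int n = 0; n < N; ++n)
      for (int c = 0; c < Cout; ++c)
        for (int ow = 0; ow < Wo; ++ow)
          for (int oh = 0; oh < Ho; ++oh)
            yp[idx4(n, c, oh, ow, N, Cout, Ho)] += b[c];
  }
  return y;
}

// [[Rcpp::export(name = ".conv2d_bw")]]
List conv2d_bw(NumericVector x, NumericVector wt, NumericVector dy,
               int stride, int pad, int groups, bool has_bias) {
  IntegerVector xd = x.attr("dim"), wd = wt.attr("dim"), yd = dy.attr("dim");
  int N = xd[0], C = xd[1], H = xd[2], W = xd[3];
  int Cout = wd[0], Cg = wd[1], kh = wd[2], kw = wd[3];
  int Ho = yd[2], Wo = yd[3];
  int Coutg = Cout / groups;
  NumericVector dx((R_xlen_t)N * C * H * W);
  dx.attr("dim") = xd;
  NumericVector dwt((R_xlen_t)Cout * Cg * kh * kw);
  dwt.attr("dim") = wd;
  NumericVector db(Cout);
  const double* xp = x.begin();
  const double* dyp = dy.begin();
  std::vector<arma::mat> Wms, dWms;
  for (int g = 0; g < groups; ++g) {
    Wms.push_back(weight_mat(wt.begin(), g, Cout, Cg, kh, kw, Coutg));
    dWms.push_back(arma::mat(Coutg, (R_xlen_t)Cg * kh * kw, arma::fill::zeros));
  }
  arma::mat col((R_xlen_t)Cg * kh * kw, (R_xlen_t)Ho * Wo);
  arma::mat dout(Coutg, (R_xlen_t)Ho * Wo);
  for (int n = 0; n < N; ++n) {
    for (int g = 0; g < groups; ++g) {
      im2col(xp, n, N, C, H, W, g * Cg, Cg, kh, kw, stride, pad, Ho, Wo, col);
      for (int co = 0; co < Coutg; ++co) {
        int c = g * Coutg + co;
        for (int ow = 0; ow < Wo; ++ow)
          for (int oh = 0; oh < Ho; ++oh)
            dout(co, oh + (R_xlen_t)Ho * ow) = dyp[idx4(n, c, oh, ow, N, Cout, Ho)];
      }
      dWms[g] += dout * col.t();
      arma::mat dcol = Wms[g].t() * dout;
      col2im_add(dx.begin(), n, N, C, H, W, g * Cg, Cg, kh, kw, stride, pad,
                 Ho, Wo, dcol);
    }
  }
  for (int g = 0; g < groups; ++g)
    for (int col_i = 0; col_i < (int)((R_xlen_t)Cg * kh * kw); ++col_i)
      for (int co = 0; co < Coutg; ++co) {
        int c = g * Coutg + co;
        int cl = col_i / (kh * kw), rem = col_i % (kh * kw);
        int ki = rem / kw, kj = rem % kw;
        R_xlen_t wi = (R_xlen_t)c + (R_xlen_t)Cout *
          ((R_xlen_t)cl + (R_xlen_t)Cg * ((R_xlen_t)ki + (R_xlen_t)kh * kj));
        dwt[wi] = dWms[g](co, col_i);
      }
  if (has_bias) {
    for (int n = 0; n < N; ++n)
      for (int c = 0; c < Cout; ++c)
        for (int ow = 0; ow < Wo; ++ow)
          for (int oh = 0; oh < Ho; ++oh)
            db[c] += dyp[idx4(n, c, oh, ow, N, Cout, Ho)];
  }
  return List::create(_["dx"] = dx, _["dw"] = dwt, _["db"] = db);
}

// [[Rcpp::export(name = ".maxpool2d_fw")]]
List maxpool2d_fw(NumericVector x, int k, int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  int N = xd[0], C = xd[1], H = xd[2], W = xd[3];
  int Ho = (H + 2 * pad - k) / stride + 1;
  int Wo = (W + 2 * pad - k) / stride + 1;
  NumericVector y((R_xlen_t)N * C * Ho * Wo);
  y.attr("dim") = IntegerVector::create(N, C, Ho, Wo);
  IntegerVector am((R_xlen_t)N * C * Ho * Wo);  // 0-based argmax into x, -1 if all padded
  const double* xp = x.begin();
  double* yp = y.begin();
  for (int ow = 0; ow < Wo; ++ow)
    for (int oh = 0; oh < Ho; ++oh)
      for (int c = 0; c < C; ++c)
        for (int n = 0; n < N; ++n) {
          double best = -INFINITY; R_xlen_t bi = -1;
          for (int ki = 0; ki < k; ++ki) {
            int h = oh * stride - pad + ki;
            if (h < 0 || h >= H) continue;
            for (int kj = 0; kj < k; ++kj) {
              int w = ow * stride - pad + kj;
              if (w < 0 || w >= W) continue;
              R_xlen_t xi = idx4(n, c, h, w, N, C, H);
              if (xp[xi] > best) { best = xp[xi]; bi = xi; }
            }
          }
          R_xlen_t yi = idx4(n, c, oh, ow, N, C, Ho);
          yp[yi] = (bi >= 0) ? best : 0.0;
          am[yi] = (int)bi;
        }
  return List::create(_["y"] = y, _["argmax"] = am);
}

// [[Rcpp::export(name = ".maxpool2d_bw")]]
NumericVector maxpool2d_bw(NumericVector dy, IntegerVector argmax,
                           IntegerVector xdim) {
  R_xlen_t nx = (R_xlen_t)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  NumericVector dx(nx);
  dx.attr("dim") = xdim;
  for (R_xlen_t i = 0; i < dy.size(); ++i)
    if (argmax[i] >= 0) dx[argmax[i]] += dy[i];
  return dx;
}

// [[Rcpp::export(name = ".upsample2x_fw")]]
NumericVector upsample2x_fw(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  int N = xd[0], C = xd[1], H = xd[2], W = xd[3];
  NumericVector y((R_xlen_t)N * C * 2 * H * 2 * W);
  y.attr("dim") = IntegerVector::create(N, C, 2 * H, 2 * W);
  const double* xp = x.begin(); double* yp = y.begin();
  for (int w = 0; w < 2 * W; ++w)
    for (int h = 0; h < 2 * H; ++h)
      for (int c = 0; c < C; ++c)
        for (int n = 0; n < N; ++n)
          yp[idx4(n, c, h, w, N, C, 2 * H)] =
            xp[idx4(n, c, h / 2, w / 2, N, C, H)];
  return y;
}

// [[Rcpp::export(name = ".upsample2x_bw")]]
NumericVector upsample2x_bw(NumericVector dy) {
  IntegerVector yd = dy.attr("dim");
  int N = yd[0], C = yd[1], H2 = yd[2], W2 = yd[3];
  int H = H2 / 2, W = W2 / 2;
  NumericVector dx((R_xlen_t)N * C * H * W);
  dx.attr("dim") = IntegerVector::create(N, C, H, W);
  const double* dyp = dy.begin(); double* dxp = dx.begin();
  for (int w = 0; w < W2; ++w)
    for (int h = 0; h < H2; ++h)
      for (int c = 0; c < C; ++c)
        for (int n = 0; n < N; ++n)
          dxp[idx4(n, c, h / 2, w / 2, N, C, H)] +=
            dyp[idx4(n, c, h, w, N, C, H2)];
  return dx;
}

// Bilinear resize of an H x W x C image array (image space, not NCHW).
// [[Rcpp::export(name = ".resize_bilinear")]]
NumericVector resize_bilinear(NumericVector img, int out_h, int out_w) {
  IntegerVector d = img.attr("dim");
  int H = d[0], W = d[1], C = d[2];
  NumericVector out((R_xlen_t)out_h * out_w * C);
  out.attr("dim") = IntegerVector::create(out_h, out_w, C);
  const double* ip = img.begin(); double* op = out.begin();
  double sh = (double)H / out_h, sw = (double)W / out_w;
  for (int c = 0; c < C; ++c)
    for (int ow = 0; ow < out_w; ++ow) {
      double fw = (ow + 0.5) * sw - 0.5;
      int w0 = (int)std::floor(fw); double aw = fw - w0;
      int w0c = std::min(std::max(w0, 0), W - 1);
      int w1c = std::min(std::max(w0 + 1, 0), W - 1);
      for (int oh = 0; oh < out_h; ++oh) {
        double fh = (oh + 0.5) * sh - 0.5;
        int h0 = (int)std::floor(fh); double ah = fh - h0;
        int h0c = std::min(std::max(h0, 0), H - 1);
        int h1c = std::min(std::max(h0 + 1, 0), H - 1);
        R_xlen_t base = (R_xlen_t)H * W * c;
        double v00 = ip[base + h0c + (R_xlen_t)H * w0c];
        double v01 = ip[base + h0c + (R_xlen_t)H * w1c];
        double v10 = ip[base + h1c + (R_xlen_t)H * w0c];
        double v11 = ip[base + h1c + (R_xlen_t)H * w1c];
        op[oh + (R_xlen_t)out_h * ow + (R_xlen_t)out_h * out_w * c] =
          (1 - ah) * ((1 - aw) * v00 + aw * v01) +
          ah * ((1 - aw) * v10 + aw * v11);
      }
    }
  return out;
}
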