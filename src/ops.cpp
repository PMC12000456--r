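#include <Rcpp.h>
using namespace Rcpp;

// Low-level tensor kernels for the NN engine. All image tensors are R arrays
// with dim (H, W, C, N), column-major, 0-based here. Convolutions are stride-1;
// spatial reduction is done by 2x2 max-pooling.

// Patch matrix for stride-1 convolution with zero padding `pad`.
// Output: (N*Ho*Wo) x (kh*kw*C); row = ho + Ho*(wo + Wo*n), col = i + kh*(j + kw*c).
// The column order matches a weight array of dim (kh, kw, C, Cout) flattened
// column-major into a (kh*kw*C) x Cout matrix.
// [[Rcpp::export]]
NumericMatrix im2col_cpp(NumericVector x, int H, int W, int C, int N,
                         int kh, int kw, int pad) {
  int Ho = H + 2 * pad - kh + 1;
  int Wo = W + 2 * pad - kw + 1;
  if (Ho < 1 || Wo < 1) stop("kernel larger than padded input");
  R_xlen_t nrow = (R_xlen_t)N * Ho * Wo;
  NumericMatrix out(nrow, kh * kw * C);
  double *po = out.begin();
  const double *px = x.begin();
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        int col = i + kh * (j + kw * c);
        double *pcol = po + (R_xlen_t)col * nrow;
        for (int n = 0; n < N; ++n) {
          for (int wo = 0; wo < Wo; ++wo) {
            int wi = wo + j - pad;
            R_xlen_t rowbase = (R_xlen_t)Ho * (wo + (R_xlen_t)Wo * n);
            if (wi < 0 || wi >= W) {
              for (int ho = 0; ho < Ho; ++ho) pcol[rowbase + ho] = 0.0;
            } else {
              const double *pxb =
                px + (R_xlen_t)H * (wi + (R_xlen_t)W * (c + (R_xlen_t)C * n));
              for (int ho = 0; ho < Ho; ++ho) {
                int hi = ho + i - pad;
                pcol[rowbase + ho] = (hi < 0 || hi >= H) ? 0.0 : pxb[hi];
              }
            }
          }
        }
      }
    }
  }
  return out;
}

// Adjoint of im2col_cpp: scatter patch-gradients back onto the input tensor.
// [[Rcpp::export]]
NumericVector col2im_cpp(NumericMatrix cols, int H, int W, int C, int N,
                         int kh, int kw, int pad) {
  int Ho = H + 2 * pad - kh + 1;
  int Wo = W + 2 * pad - kw + 1;
  R_xlen_t nrow = (R_xlen_t)N * Ho * Wo;
  NumericVector x((R_xlen_t)H * W * C * N);
  double *px = x.begin();
  const double *po = cols.begin();
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        int col = i + kh * (j + kw * c);
        const double *pcol = po + (R_xlen_t)col * nrow;
        for (int n = 0; n < N; ++n) {
          for (int wo = 0; wo < Wo; ++wo) {
            int wi = wo + j - pad;
            if (wi < 0 || wi >= W) continue;
            R_xlen_t rowbase = (R_xlen_t)Ho * (wo + (R_xlen_t)Wo * n);
            double *pxb =
              px + (R_xlen_t)H * (wi + (R_xlen_t)W * (c + (R_xlen_t)C * n));
            for (int ho = 0; ho < Ho; ++ho) {
              int hi = ho + i - pad;
              if (hi < 0 || hi >= H) continue;
              pxb[hi] += pcol[rowbase + ho];
            }
          }
        }
      }
    }
  }
  return x;
}

// 2x2 max-pooling, stride 2. H and W must be even. Returns the pooled tensor
// and the 0-based flat index of each winner (for the backward pass).
// [[Rcpp::export]]
List maxpool_cpp(NumericVector x, int H, int W, int C, int N) {
  if (H % 2 || W % 2) stop("max-pooling needs even spatial dims");
  int Ho = H / 2, Wo = W / 2;
  R_xlen_t olen = (R_xlen_t)Ho * Wo * C * N;
  NumericVector out(olen);
  IntegerVector arg(olen);
  const double *px = x.begin();
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      R_xlen_t xplane = (R_xlen_t)H * W * (c + (R_xlen_t)C * n);
      R_xlen_t oplane = (R_xlen_t)Ho * Wo * (c + (R_xlen_t)C * n);
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          R_xlen_t base = xplane + 2 * ho + (R_xlen_t)H * (2 * wo);
          R_xlen_t idx[4] = {base, base + 1, base + H, base + H + 1};
          R_xlen_t best = idx[0];
          double bv = px[best];
          for (int q = 1; q < 4; ++q)
            if (px[idx[q]] > bv) { bv = px[idx[q]]; best = idx[q]; }
          R_xlen_t o = oplane + ho + (R_xlen_t)Ho * wo;
          out[o] = bv;
          arg[o] = (int)best;
        }
      }
    }
  }
  return List::create(_["out"] = out, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericVector maxpool_bwd_cpp(NumericVector dout, IntegerVector argmax,
                              double xlen) {
  NumericVector dx((R_xlen_t)xlen);
  for (R_xlen_t i = 0; i < dout.size(); ++i) dx[argmax[i]] += dout[i];
  return dx;
}

// Bilinear resize with the align-corners convention: output pixel (ho, wo)
// samples input position ho*(H-1)/(Ho-1). Deterministic; used both for image
// loading and for upsampling Grad-CAM maps to input resolution.
// [[Rcpp::export]]
NumericVector resize_bilinear_cpp(NumericVector x, int H, int W, int C, int N,
                                  int Ho, int Wo) {
  NumericVector out((R_xlen_t)Ho * Wo * C * N);
  double sh = (Ho > 1) ? (double)(H - 1) / (Ho - 1) : 0.0;
  double sw = (Wo > 1) ? (double)(W - 1) / (Wo - 1) : 0.0;
  const double *px = x.begin();
  double *po = out.begin();
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double *pp = px + (R_xlen_t)H * W * (c + (R_xlen_t)C * n);
      double *op = po + (R_xlen_t)Ho * Wo * (c + (R_xlen_t)C * n);
      for (int wo = 0; wo < Wo; ++wo) {
        double w = wo * sw;
        int w0 = (int)w;
        if (w0 > W - 1) w0 = W - 1;
        int w1 = (w0 < W - 1) ? w0 + 1 : w0;
        double fw = w - w0;
        for (int ho = 0; ho < Ho; ++ho) {
          double h = ho * sh;
          int h0 = (int)h;
          if (h0 > H - 1) h0 = H - 1;
          int h1 = (h0 < H - 1) ? h0 + 1 : h0;
          double fh = h - h0;
          double v =
            (1 - fh) * (1 - fw) * pp[h0 + (R_xlen_t)H * w0] +
            fh * (1 - fw)       * pp[h1 + (R_xlen_t)H * w0] +
            (1 - fh) * fw       * pp[h0 + (R_xlen_t)H * w1] +
            fh * fw             * pp[h1 + (R_xlen_t)H * w1];
          op[ho + (R_xlen_t)Ho * wo] = v;
        }
      }
    }
  }
  return out;
}
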