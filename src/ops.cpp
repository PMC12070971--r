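#include <Rcpp.h>
using namespace Rcpp;

// Feature maps are column-major (H, W, C) arrays: x[h + H*w + H*W*c].
// im2col row index: di + k*dj + k*k*c; column index: ho + Ho*wo.

static inline int out_size(int n, int k, int stride, int pad) {
  return (n + 2 * pad - k) / stride + 1;
}

// [[Rcpp::export]]
NumericMatrix cpp_im2col(NumericVector x, int H, int W, int C,
                         int k, int stride, int pad) {
  const int Ho = out_size(H, k, stride, pad);
  const int Wo = out_size(W, k, stride, pad);
  NumericMatrix out(k * k * C, Ho * Wo);
  const double* px = x.begin();
  double* po = out.begin();
  const int nrow = k * k * C;
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const int q = ho + Ho * wo;
      double* col = po + (size_t)q * nrow;
      const int h0 = ho * stride - pad;
      const int w0 = wo * stride - pad;
      for (int c = 0; c < C; ++c) {
        const double* xc = px + (size_t)c * H * W;
        for (int dj = 0; dj < k; ++dj) {
          const int w = w0 + dj;
          for (int di = 0; di < k; ++di) {
            const int h = h0 + di;
            double v = 0.0;
            if (h >= 0 && h < H && w >= 0 && w < W) v = xc[h + H * w];
            col[di + k * dj + k * k * c] = v;
          }
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_col2im(NumericMatrix cols, int H, int W, int C,
                         int k, int stride, int pad) {
  const int Ho = out_size(H, k, stride, pad);
  const int Wo = out_size(W, k, stride, pad);
  NumericVector x((size_t)H * W * C);
  double* px = x.begin();
  const double* pc = cols.begin();
  const int nrow = k * k * C;
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const int q = ho + Ho * wo;
      const double* col = pc + (size_t)q * nrow;
      const int h0 = ho * stride - pad;
      const int w0 = wo * stride - pad;
      for (int c = 0; c < C; ++c) {
        double* xc = px + (size_t)c * H * W;
        for (int dj = 0; dj < k; ++dj) {
          const int w = w0 + dj;
          if (w < 0 || w >= W) continue;
          for (int di = 0; di < k; ++di) {
            const int h = h0 + di;
            if (h < 0 || h >= H) continue;
            xc[h + H * w] += col[di + k * dj + k * k * c];
          }
        }
      }
    }
  }
  x.attr("dim") = IntegerVector::create(H, W, C);
  return x;
}

// Depthwise convolution: weights wt is (k*k, C), one kernel per channel.
// [[Rcpp::export]]
NumericVector cpp_dwconv(NumericVector x, int H, int W, int C,
                         NumericMatrix wt, int k, int stride, int pad) {
  const int Ho = out_size(H, k, stride, pad);
  const int Wo = out_size(W, k, stride, pad);
  NumericVector y((size_t)Ho * Wo * C);
  const double* px = x.begin();
  double* py = y.begin();
  for (int c = 0; c < C; ++c) {
    const double* xc = px + (size_t)c * H * W;
    const double* wc = &wt(0, c);
    double* yc = py + (size_t)c * Ho * Wo;
    for (int wo = 0; wo < Wo; ++wo) {
      const int w0 = wo * stride - pad;
      for (int ho = 0; ho < Ho; ++ho) {
        const int h0 = ho * stride - pad;
        double acc = 0.0;
        for (int dj = 0; dj < k; ++dj) {
          const int w = w0 + dj;
          if (w < 0 || w >= W) continue;
          for (int di = 0; di < k; ++di) {
            const int h = h0 + di;
            if (h < 0 || h >= H) continue;
            acc += xc[h + H * w] * wc[di + k * dj];
          }
        }
        yc[ho + Ho * wo] = acc;
      }
    }
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, C);
  return y;
}

// Backward of depthwise conv: returns list(dx, dw).
// [[Rcpp::export]]
List cpp_dwconv_bw(NumericVector x, int H, int W, int C,
                   NumericMatrix wt, int k, int stride, int pad,
                   NumericVector dy) {
  const int Ho = out_size(H, k, stride, pad);
  const int Wo = out_size(W, k, stride, pad);
  NumericVector dx((size_t)H * W * C);
  NumericMatrix dw(k * k, C);
  const double* px = x.begin();
  const double* pdy = dy.begin();
  double* pdx = dx.begin();
  for (int c = 0; c < C; ++c) {
    const double* xc = px + (size_t)c * H * W;
    const double* dyc = pdy + (size_t)c * Ho * Wo;
    const double* wc = &wt(0, c);
    double* dxc = pdx + (size_t)c * H * W;
    double* dwc = &dw(0, c);
    for (int wo = 0; wo < Wo; ++wo) {
      const int w0 = wo * stride - pad;
      for (int ho = 0; ho < Ho; ++ho) {
        const int h0 = ho * stride - pad;
        const double g = dyc[ho + Ho * wo];
        if (g == 0.0) continue;
        for (int dj = 0; dj < k; ++dj) {
          const int w = w0 + dj;
          if (w < 0 || w >= W) continue;
          for (int di = 0; di < k; ++di) {
            const int h = h0 + di;
            if (h < 0 || h >= H) continue;
            dxc[h + H * w] += g * wc[di + k * dj];
            dwc[di + k * dj] += g * xc[h + H * w];
          }
        }
      }
    }
  }
  dx.attr("dim") = IntegerVector::create(H, W, C);
  return List::create(_["dx"] = dx, _["dw"] = dw);
}

// Max pooling with argmax indices (1-based, into the (H,W,C) input).
// [[Rcpp::export]]
List cpp_maxpool(NumericVector x, int H, int W, int C,
                 int k, int stride, int pad) {
  const int Ho = out_size(H, k, stride, pad);
  const int Wo = out_size(W, k, stride, pad);
  NumericVector y((size_t)Ho * Wo * C);
  IntegerVector idx((size_t)Ho * Wo * C);
  const double* px = x.begin();
  for (int c = 0; c < C; ++c) {
    const double* xc = px + (size_t)c * H * W;
    for (int wo = 0; wo < Wo; ++wo) {
      const int w0 = wo * stride - pad;
      for (int ho = 0; ho < Ho; ++ho) {
        const int h0 = ho * stride - pad;
        double best = R_NegInf;
        int besti = -1;
        for (int dj = 0; dj < k; ++dj) {
          const int w = w0 + dj;
          if (w < 0 || w >= W) continue;
          for (int di = 0; di < k; ++di) {
            const int h = h0 + di;
            if (h < 0 || h >= H) continue;
            const double v = xc[h + H * w];
            if (v > best) { best = v; besti = h + H * w; }
          }
        }
        const size_t o = (size_t)c * Ho * Wo + ho + Ho * wo;
        y[o] = best;
        idx[o] = besti + 1 + c * H * W;
      }
    }
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, C);
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bw(NumericVector dy, IntegerVector idx,
                             int H, int W, int C) {
  NumericVector dx((size_t)H * W * C);
  for (R_xlen_t i = 0; i < dy.size(); ++i) dx[idx[i] - 1] += dy[i];
  dx.attr("dim") = IntegerVector::create(H, W, C);
  return dx;
}
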