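#include <Rcpp.h>
using namespace Rcpp;

// Feature blocks are stored as dense column-major arrays with dim (H, W, C, N).
// im2col lays a (k x k x C) patch per output position into one column so the
// convolution reduces to a single BLAS matrix product on the R side.

// [[Rcpp::export(name = ".cpp_im2col")]]
NumericMatrix cpp_im2col(NumericVector x, int H, int W, int C, int N,
                         int k, int stride, int pad) {
  const int oh = (H + 2 * pad - k) / stride + 1;
  const int ow = (W + 2 * pad - k) / stride + 1;
  const int rows = k * k * C;
  const long L = (long)oh * ow * N;
  NumericMatrix col(rows, L);
  const double *px = x.begin();
  double *pc = col.begin();

  for (int n = 0; n < N; ++n) {
    for (int wj = 0; wj < ow; ++wj) {
      for (int hi = 0; hi < oh; ++hi) {
        long colIdx = (long)hi + (long)oh * wj + (long)oh * ow * n;
        double *dst = pc + colIdx * rows;
        int h0 = hi * stride - pad;
        int w0 = wj * stride - pad;
        for (int c = 0; c < C; ++c) {
          const double *src = px + (long)H * W * c + (long)H * W * C * n;
          for (int kj = 0; kj < k; ++kj) {
            int wcur = w0 + kj;
            for (int ki = 0; ki < k; ++ki) {
              int hcur = h0 + ki;
              double v = 0.0;
              if (hcur >= 0 && hcur < H && wcur >= 0 && wcur < W)
                v = src[hcur + (long)H * wcur];
              dst[ki + k * kj + k * k * c] = v;
            }
          }
        }
      }
    }
  }
  return col;
}

// [[Rcpp::export(name = ".cpp_col2im")]]
NumericVector cpp_col2im(NumericMatrix col, int H, int W, int C, int N,
                         int k, int stride, int pad) {
  const int oh = (H + 2 * pad - k) / stride + 1;
  const int ow = (W + 2 * pad - k) / stride + 1;
  const int rows = k * k * C;
  NumericVector out((long)H * W * C * N);
  const double *pc = col.begin();
  double *px = out.begin();

  for (int n = 0; n < N; ++n) {
    for (int wj = 0; wj < ow; ++wj) {
      for (int hi = 0; hi < oh; ++hi) {
        long colIdx = (long)hi + (long)oh * wj + (long)oh * ow * n;
        const double *src = pc + colIdx * rows;
        int h0 = hi * stride - pad;
        int w0 = wj * stride - pad;
        for (int c = 0; c < C; ++c) {
          double *dst = px + (long)H * W * c + (long)H * W * C * n;
          for (int kj = 0; kj < k; ++kj) {
            int wcur = w0 + kj;
            if (wcur < 0 || wcur >= W) continue;
            for (int ki = 0; ki < k; ++ki) {
              int hcur = h0 + ki;
              if (hcur < 0 || hcur >= H) continue;
              dst[hcur + (long)H * wcur] += src[ki + k * kj + k * k * c];
            }
          }
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(H, W, C, N);
  return out;
}

// Max pooling; records the argmax (1-based linear index into x) for backprop.
// [[Rcpp::export(name = ".cpp_maxpool")]]
List cpp_maxpool(NumericVector x, int H, int W, int C, int N,
                 int k, int stride, int pad) {
  const int oh = (H + 2 * pad - k) / stride + 1;
  const int ow = (W + 2 * pad - k) / stride + 1;
  NumericVector out((long)oh * ow * C * N);
  IntegerVector arg((long)oh * ow * C * N);
  const double *px = x.begin();
  double *po = out.begin();
  int *pa = arg.begin();

  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      
      for (int wj = 0; wj < ow; ++wj) {
        for (int hi = 0; hi < oh; ++hi) {
          int h0 = hi * stride - pad;
          int w0 = wj * stride - pad;
          double best = R_NegInf;
          long bestIdx = -1;
          for (int kj = 0; kj < k; ++kj) {
            int wcur = w0 + kj;
            if (wcur < 0 || wcur >= W) continue;
            for (int ki = 0; ki < k; ++ki) {
              int hcur = h0 + ki;
              if (hcur < 0 || hcur >= H) continue;
              long idx = hcur + (long)H * wcur + (long)H * W * c +
                         (long)H * W * C * n;
              if (px[idx] > best) { best = px[idx]; bestIdx = idx; }
            }
          }
          long oidx = (long)hi + (long)oh * wj + (long)oh * ow * c +
                      (long)oh * ow * C * n;
          po[oidx] = best;
          pa[oidx] = (int)(bestIdx + 1);
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(oh, ow, C, N);
  return List::create(_["out"] = out, _["argmax"] = arg);
}

// [[Rcpp::export(name = ".cpp_maxpool_bwd")]]
NumericVector cpp_maxpool_bwd(NumericVector dout, IntegerVector argmax,
                              int H, int W, int C, int N) {
  NumericVector dx((long)H * W * C * N);
  const double *pd = dout.begin();
  const int *pa = argmax.begin();
  double *px = dx.begin();
  long L = dout.size();
  for (long i = 0; i < L; ++i) px[pa[i] - 1] += pd[i];
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  return dx;
}
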