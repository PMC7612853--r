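#include <Rcpp.h>
using namespace Rcpp;

// 1D convolution of a (column-major) D-dimensional array along one axis,
// with either bounded cropping or circular wrap-around.
//
// out[..., j, ...] = sum_k w[k] * x[..., j + offset + k - r, ...]
//
// where r = (length(w) - 1) / 2.  In bounded mode the caller guarantees
// offset >= r, so every tap lands inside the input (defensive skips remain
// in the generic path).  The summation order over k is fixed for every
// output element, which makes periodic convolution exactly equivariant to
// circular shifts of the input (same floating-point operations, shifted).
//
// Two layouts: along the first axis the input line is contiguous and each
// output is a direct dot product; along later axes the stride-`inner`
// layout accumulates whole contiguous panels per tap.
//
// [[Rcpp::export]]
NumericVector conv_axis_cpp(NumericVector x, IntegerVector dims, int axis,
                            NumericVector w, int offset, bool periodic,
                            int n_out) {
  const int D = dims.size();
  if (axis < 0 || axis >= D) stop("axis out of range");
  const int n_in = dims[axis];
  const int L = w.size();
  const int r = (L - 1) / 2;

  R_xlen_t inner = 1, outer = 1;
  for (int a = 0; a < axis; ++a) inner *= dims[a];
  for (int a = axis + 1; a < D; ++a) outer *= dims[a];

  NumericVector out(inner * (R_xlen_t)n_out * outer);  // zero-initialised
  const double *xp = x.begin();
  const double *wp = w.begin();
  double *op = out.begin();

  if (inner == 1 && !periodic && offset >= r && offset + n_out - 1 + r < n_in) {
    // contiguous lines, all taps in range: plain dot products
    for (R_xlen_t o = 0; o < outer; ++o) {
      const double *xo = xp + o * n_in;
      double *oo = op + o * n_out;
      for (int j = 0; j < n_out; ++j) {
        const double *xs = xo + j + offset - r;
        double s = 0.0;
        for (int k = 0; k < L; ++k) s += wp[k] * xs[k];
        oo[j] = s;
      }
    }
    return out;
  }

  if (inner == 1) {
    for (R_xlen_t o = 0; o < outer; ++o) {
      const double *xo = xp + o * n_in;
      double *oo = op + o * n_out;
      for (int j = 0; j < n_out; ++j) {
        double s = 0.0;
        const long base = (long)j + offset - r;
        for (int k = 0; k < L; ++k) {
          long src = base + k;
          if (periodic) {
            src %= n_in;
            if (src < 0) src += n_in;
          } else if (src < 0 || src >= n_in) {
            continue;
          }
          s += wp[k] * xo[src];
        }
        oo[j] = s;
      }
    }
    return out;
  }

  for (R_xlen_t o = 0; o < outer; ++o) {
    const double *xo = xp + o * inner * n_in;
    double *oo = op + o * inner * n_out;
    for (int j = 0; j < n_out; ++j) {
      double *orow = oo + (R_xlen_t)j * inner;
      for (int k = 0; k < L; ++k) {
        long src = (long)j + offset + k - r;
        if (periodic) {
          src %= n_in;
          if (src < 0) src += n_in;
        } else if (src < 0 || src >= n_in) {
          continue;
        }
        const double wk = wp[k];
        const double *xrow = xo + (R_xlen_t)src * inner;
        for (R_xlen_t i = 0; i < inner; ++i) orow[i] += wk * xrow[i];
      }
    }
  }
  return out;
}
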