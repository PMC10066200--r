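// 3x3 convolution forward/backward via im2col and BLAS GEMM.
// Feature maps are H x W x C arrays (column-major, matching R arrays) and
// are accessed through no-copy Armadillo views.  Patch-matrix column layout
// is offset-major (window offset outer, input channel inner); weights are
// (9 * Cin) x Cout with rows in the same order.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// gather the window-offset columns of x into cols, zero-filling outside the
// image ("same" zero padding), for output positions on the stride lattice
static void im2col3(const cube& x, mat& cols, const int stride) {
  const int h = x.n_rows, w = x.n_cols, cc = x.n_slices;
  const int ho = h / stride, wo = w / stride;
  for (int c = 0; c < cc; ++c) {       // channel-outer: slice stays cached
    const mat& ps = x.slice(c);
    for (int off = 0; off < 9; ++off) {
      const int di = off % 3 - 1, dj = off / 3 - 1;
      const int i0 = std::max(0, -di);
      const int i1 = std::min(ho, di < 0 ? ho : (h - di + stride - 1) / stride);
      double* dst = cols.colptr(off * cc + c);
      for (int j = 0; j < wo; ++j) {
        const int sc = j * stride + dj;
        double* dstj = dst + j * ho;
        if (sc < 0 || sc >= w) {
          std::memset(dstj, 0, ho * sizeof(double));
          continue;
        }
        const double* src = ps.colptr(sc) + di;
        for (int i = 0; i < i0; ++i) dstj[i] = 0.0;
        if (stride == 1)
          std::memcpy(dstj + i0, src + i0, (i1 - i0) * sizeof(double));
        else
          for (int i = i0; i < i1; ++i) dstj[i] = src[i * stride];
        for (int i = i1; i < ho; ++i) dstj[i] = 0.0;
      }
    }
  }
}

// [[Rcpp::export]]
Rcpp::List conv_fwd_cpp(Rcpp::NumericVector x_, Rcpp::NumericMatrix W_,
                        Rcpp::NumericVector b_, const int stride) {
  Rcpp::IntegerVector d = x_.attr("dim");
  const int h = d[0], w = d[1], cc = d[2];
  const int ho = h / stride, wo = w / stride, n = ho * wo;
  const int cout = W_.ncol();
  const cube x(x_.begin(), h, w, cc, false);
  const mat W(W_.begin(), W_.nrow(), cout, false);
  const vec b(b_.begin(), cout, false);

  Rcpp::NumericMatrix cols_(n, 9 * cc);
  mat cols(cols_.begin(), n, 9 * cc, false);
  im2col3(x, cols, stride);

  Rcpp::NumericVector y_(n * cout);
  mat y(y_.begin(), n, cout, false);
  y = cols * W;
  y.each_row() += b.t();
  y_.attr("dim") = Rcpp::IntegerVector::create(ho, wo, cout);
  return Rcpp::List::create(Rcpp::Named("y") = y_,
                            Rcpp::Named("cols") = cols_);
}

// [[Rcpp::export]]
Rcpp::List conv_bwd_cpp(Rcpp::NumericVector dy_, Rcpp::NumericMatrix cols_,
                        Rcpp::NumericMatrix W_, const int h, const int w,
                        const int cin, const int stride) {
  const int ho = h / stride, wo = w / stride, n = ho * wo;
  Rcpp::IntegerVector d = dy_.attr("dim");
  const int cout = d[2];
  const mat dym(dy_.begin(), n, cout, false);
  const mat cols(cols_.begin(), n, 9 * cin, false);
  const mat W(W_.begin(), 9 * cin, cout, false);

  Rcpp::NumericMatrix dW_(9 * cin, cout);
  mat dW(dW_.begin(), 9 * cin, cout, false);
  dW = cols.t() * dym;
  Rcpp::NumericVector db_(cout);
  vec db(db_.begin(), cout, false);
  db = sum(dym, 0).t();

  mat dcols = dym * W.t();
  Rcpp::NumericVector dx_(h * w * cin);          // zero-initialized
  cube dx(dx_.begin(), h, w, cin, false);
  for (int c = 0; c < cin; ++c) {      // channel-outer: slice stays cached
    mat& ps = dx.slice(c);
    for (int off = 0; off < 9; ++off) {
      const int di = off % 3 - 1, dj = off / 3 - 1;
      const int i0 = std::max(0, -di);
      const int i1 = std::min(ho, di < 0 ? ho : (h - di + stride - 1) / stride);
      const double* src = dcols.colptr(off * cin + c);
      for (int j = 0; j < wo; ++j) {
        const int sc = j * stride + dj;
        if (sc < 0 || sc >= w) continue;
        double* dst = ps.colptr(sc) + di;
        const double* srcj = src + j * ho;
        for (int i = i0; i < i1; ++i) dst[i * stride] += srcj[i];
      }
    }
  }
  dx_.attr("dim") = Rcpp::IntegerVector::create(h, w, cin);
  return Rcpp::List::create(Rcpp::Named("dW") = dW_,
                            Rcpp::Named("db") = db_,
                            Rcpp::Named("dx") = dx_);
}
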