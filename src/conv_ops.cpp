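// Same-padded 2-D convolution (cross-correlation) forward and backward,
// implemented as im2col + GEMM. Feature maps are H x W x C arma::cubes,
// matching R arrays with dim c(H, W, C). Kernels are R arrays with
// dim c(k, k, Cin, Cout), flattened column-major into a (k*k*Cin) x Cout
// matrix so no reordering is needed on either side.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static mat im2col_same(const cube& x, const int k) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int pad = (k - 1) / 2;
  mat K(k * k * C, H * W, fill::zeros);
  for (int c = 0; c < C; ++c) {
    const mat& xc = x.slice(c);
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        const int r = di + k * dj + k * k * c;
        for (int j = 0; j < W; ++j) {
          const int jj = j + dj - pad;
          if (jj < 0 || jj >= W) continue;
          const int ilo = std::max(0, pad - di);
          const int ihi = std::min(H, H + pad - di);
          for (int i = ilo; i < ihi; ++i) {
            K(r, i + H * j) = xc(i + di - pad, jj);
          }
        }
      }
    }
  }
  return K;
}

// scatter-add of column space back to image space (adjoint of im2col_same)
static cube col2im_same(const mat& K, const int H, const int W, const int C,
                        const int k) {
  const int pad = (k - 1) / 2;
  cube x(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    mat& xc = x.slice(c);
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        const int r = di + k * dj + k * k * c;
        for (int j = 0; j < W; ++j) {
          const int jj = j + dj - pad;
          if (jj < 0 || jj >= W) continue;
          const int ilo = std::max(0, pad - di);
          const int ihi = std::min(H, H + pad - di);
          for (int i = ilo; i < ihi; ++i) {
            xc(i + di - pad, jj) += K(r, i + H * j);
          }
        }
      }
    }
  }
  return x;
}

// [[Rcpp::export]]
arma::cube conv2d_fwd_cpp(const arma::cube& x, const Rcpp::NumericVector& w,
                          const arma::vec& b) {
  Rcpp::IntegerVector wd = w.attr("dim");
  const int k = wd[0], Cin = wd[2], Cout = wd[3];
  if ((int)x.n_slices != Cin)
    Rcpp::stop("conv2d: input has %d channels, kernel expects %d",
               (int)x.n_slices, Cin);
  const int H = x.n_rows, W = x.n_cols;
  const mat Wm(const_cast<double*>(w.begin()), k * k * Cin, Cout, false, true);
  const mat K = im2col_same(x, k);
  mat Y = Wm.t() * K;  // Cout x (H*W)
  Y.each_col() += b;
  cube out(H, W, Cout);
  for (int c = 0; c < Cout; ++c)
    out.slice(c) = reshape(Y.row(c).t(), H, W);
  return out;
}

// [[Rcpp::export]]
Rcpp::List conv2d_bwd_cpp(const arma::cube& x, const Rcpp::NumericVector& w,
                          const arma::cube& dy) {
  Rcpp::IntegerVector wd = w.attr("dim");
  const int k = wd[0], Cin = wd[2], Cout = wd[3];
  const int H = x.n_rows, W = x.n_cols;
  const mat Wm(const_cast<double*>(w.begin()), k * k * Cin, Cout, false, true);
  mat Gy(Cout, H * W);
  for (int c = 0; c < Cout; ++c)
    Gy.row(c) = reshape(dy.slice(c), 1, H * W);
  const mat K = im2col_same(x, k);
  mat dWm = K * Gy.t();           // (k*k*Cin) x Cout, same layout as w
  vec db = sum(Gy, 1);
  cube dx = col2im_same(Wm * Gy, H, W, Cin, k);
  Rcpp::NumericVector dw(dWm.begin(), dWm.end());
  dw.attr("dim") = wd;
  return Rcpp::List::create(Rcpp::Named("dx") = dx, Rcpp::Named("dw") = dw,
                            Rcpp::Named("db") = db);
}
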