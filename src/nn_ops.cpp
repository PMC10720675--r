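// Convolution primitives for the segmentation networks.
//
// Layout contract (shared with the R layer): feature maps are H x W x C
// arrays (column-major, row index fastest); 'same' stride-1 convolutions
// with zero padding; the patch matrix has the tap index running fastest
// within each input-channel block, matching the k^2*Cin x Cout weight
// matrix layout.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static arma::mat im2col_cpp(const arma::cube& x, int k, int dil) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int k2 = k * k, r = k / 2;
  arma::mat P(H * W, k2 * C);
  for (int c = 0; c < C; ++c) {
    const arma::mat& xc = x.slice(c);
    for (int jc = 0; jc < k; ++jc) {
      const int dc = (jc - r) * dil;
      for (int jr = 0; jr < k; ++jr) {
        const int dr = (jr - r) * dil;
        const int j = jc * k + jr;            // tap index, column-major taps
        double* out = P.colptr(c * k2 + j);
        // valid output rows are those with 0 <= row + dr < H: a contiguous
        // span, so each column is two zero fills plus one memcpy
        const int row0 = std::max(0, -dr), row1 = std::min(H, H - dr);
        for (int col = 0; col < W; ++col) {
          const int c2 = col + dc;
          double* o = out + col * H;
          if (c2 < 0 || c2 >= W || row1 <= row0) {
            std::fill(o, o + H, 0.0);
            continue;
          }
          const double* src = xc.colptr(c2);
          if (row0 > 0) std::fill(o, o + row0, 0.0);
          std::copy(src + row0 + dr, src + row1 + dr, o + row0);
          if (row1 < H) std::fill(o + row1, o + H, 0.0);
        }
      }
    }
  }
  return P;
}

// [[Rcpp::export(name = ".nm_conv_fwd")]]
NumericVector nm_conv_fwd(NumericVector x_, NumericMatrix W_, NumericVector b_,
                          int k, int dil) {
  IntegerVector dims = x_.attr("dim");
  const int H = dims[0], W = dims[1], C = dims[2];
  const arma::cube x(const_cast<double*>(x_.begin()), H, W, C, false, true);
  const arma::mat Wm(const_cast<double*>(W_.begin()), W_.nrow(), W_.ncol(), false, true);
  const int Cout = Wm.n_cols;
  arma::mat y;
  if (k == 1) {
    arma::mat xm(const_cast<double*>(x_.begin()), H * W, C, false, true);
    y = xm * Wm;
  } else {
    y = im2col_cpp(x, k, dil) * Wm;
  }
  for (int c = 0; c < Cout; ++c) y.col(c) += b_[c];
  NumericVector out(y.begin(), y.end());
  out.attr("dim") = IntegerVector::create(H, W, Cout);
  return out;
}

// [[Rcpp::export(name = ".nm_conv_bwd")]]
List nm_conv_bwd(NumericVector x_, NumericMatrix W_, NumericVector dy_,
                 int k, int dil) {
  IntegerVector dims = x_.attr("dim");
  const int H = dims[0], W = dims[1], C = dims[2];
  const arma::cube x(const_cast<double*>(x_.begin()), H, W, C, false, true);
  const arma::mat Wm(const_cast<double*>(W_.begin()), W_.nrow(), W_.ncol(), false, true);
  const int Cout = Wm.n_cols, k2 = k * k;
  const arma::mat dy(const_cast<double*>(dy_.begin()), H * W, Cout, false, true);

  arma::mat dW, dx;
  if (k == 1) {
    arma::mat xm(const_cast<double*>(x_.begin()), H * W, C, false, true);
    dW = xm.t() * dy;
    dx = dy * Wm.t();
  } else {
    arma::mat P = im2col_cpp(x, k, dil);
    dW = P.t() * dy;
    // dx = gather(dy) * flipped weights; tap j flips to k2 - 1 - j
    arma::mat Wf(k2 * Cout, C);
    for (int c = 0; c < C; ++c)
      for (int co = 0; co < Cout; ++co)
        for (int j = 0; j < k2; ++j)
          Wf(co * k2 + j, c) = Wm(c * k2 + (k2 - 1 - j), co);
    arma::cube dyc(const_cast<double*>(dy_.begin()), H, W, Cout, false, true);
    dx = im2col_cpp(dyc, k, dil) * Wf;
  }
  arma::rowvec db = arma::sum(dy, 0);

  NumericVector dxv(dx.begin(), dx.end());
  dxv.attr("dim") = IntegerVector::create(H, W, C);
  return List::create(_["dx"] = dxv,
                      _["dW"] = wrap(dW),
                      _["db"] = NumericVector(db.begin(), db.end()));
}
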