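// 3x3 same-padding convolution kernels for the dual-branch patch network.
// Arrays use R's column-major layout with dims (B, H, W, C); weights are
// (9, Cin, Cout) with k indexing the neighborhood offsets column-major over
// (dr, dc) in {-1,0,1}^2. Implemented as im2col + BLAS dgemm.

#include <Rcpp.h>
#include <R_ext/BLAS.h>
using namespace Rcpp;

static inline int koff_dr(int k) { return (k % 3) - 1; }
static inline int koff_dc(int k) { return (k / 3) - 1; }

// col matrix M: (B*H*W) x (9*Cin), column j = k + 9*ci holds the input
// plane ci shifted by offset k (zero outside the image).
static void im2col(const double *x, int B, int H, int Wd, int Cin,
                   double *M) {
  const R_xlen_t plane = static_cast<R_xlen_t>(B) * H * Wd;
  for (int ci = 0; ci < Cin; ++ci) {
    const double *xc = x + plane * ci;
    for (int k = 0; k < 9; ++k) {
      double *col = M + plane * (k + 9 * ci);
      const int dr = koff_dr(k), dc = koff_dc(k);
      const int h0 = std::max(0, -dr), h1 = std::min(H, H - dr);
      const int w0 = std::max(0, -dc), w1 = std::min(Wd, Wd - dc);
      std::fill(col, col + plane, 0.0);
      const int run = B * (h1 - h0);
      for (int w = w0; w < w1; ++w) {
        const double *src = xc + static_cast<R_xlen_t>(B) * ((h0 + dr) + H * (w + dc));
        double *dst = col + static_cast<R_xlen_t>(B) * (h0 + H * w);
        std::copy(src, src + run, dst);
      }
    }
  }
}

// scatter-accumulate the columns back: dX += col2im(dM)
static void col2im_acc(const double *dM, int B, int H, int Wd, int Cin,
                       double *dX) {
  const R_xlen_t plane = static_cast<R_xlen_t>(B) * H * Wd;
  for (int ci = 0; ci < Cin; ++ci) {
    double *dxc = dX + plane * ci;
    for (int k = 0; k < 9; ++k) {
      const double *col = dM + plane * (k + 9 * ci);
      const int dr = koff_dr(k), dc = koff_dc(k);
      const int h0 = std::max(0, -dr), h1 = std::min(H, H - dr);
      const int w0 = std::max(0, -dc), w1 = std::min(Wd, Wd - dc);
      const int run = B * (h1 - h0);
      for (int w = w0; w < w1; ++w) {
        double *dst = dxc + static_cast<R_xlen_t>(B) * ((h0 + dr) + H * (w + dc));
        const double *src = col + static_cast<R_xlen_t>(B) * (h0 + H * w);
        for (int i = 0; i < run; ++i) dst[i] += src[i];
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv3x3_fwd_cpp(NumericVector x, IntegerVector dims,
                              NumericVector W, NumericVector b, int Cout) {
  const int B = dims[0], H = dims[1], Wd = dims[2], Cin = dims[3];
  const R_xlen_t plane = static_cast<R_xlen_t>(B) * H * Wd;
  const int K = 9 * Cin;
  std::vector<double> M(plane * K);
  im2col(x.begin(), B, H, Wd, Cin, M.data());

  NumericVector Z(plane * Cout);
  double *zp = Z.begin();
  for (int co = 0; co < Cout; ++co)
    std::fill(zp + plane * co, zp + plane * (co + 1), b[co]);

  const int m = static_cast<int>(plane), n = Cout, kk = K;
  const double one = 1.0;
  // Z += M %*% W  (W viewed as (9*Cin) x Cout)
  F77_CALL(dgemm)("N", "N", &m, &n, &kk, &one, M.data(), &m,
                  REAL(W), &kk, &one, zp, &m FCONE FCONE);
  Z.attr("dim") = IntegerVector::create(B, H, Wd, Cout);
  return Z;
}

// [[Rcpp::export]]
List conv3x3_bwd_cpp(NumericVector dZ, NumericVector x, IntegerVector dims,
                     NumericVector W, int Cout) {
  const int B = dims[0], H = dims[1], Wd = dims[2], Cin = dims[3];
  const R_xlen_t plane = static_cast<R_xlen_t>(B) * H * Wd;
  const int K = 9 * Cin;
  std::vector<double> M(plane * K);
  im2col(x.begin(), B, H, Wd, Cin, M.data());

  NumericVector dW(K * Cout), db(Cout), dX(plane * Cin);
  const double *dzp = dZ.begin();
  for (int co = 0; co < Cout; ++co) {
    const double *zc = dzp + plane * co;
    double acc = 0.0;
    for (R_xlen_t i = 0; i < plane; ++i) acc += zc[i];
    db[co] = acc;
  }

  const int m = static_cast<int>(plane);
  const double one = 1.0, zero = 0.0;
  // dW = t(M) %*% dZ : (K x plane)(plane x Cout)
  F77_CALL(dgemm)("T", "N", &K, &Cout, &m, &one, M.data(), &m,
                  const_cast<double *>(dzp), &m, &zero, REAL(dW), &K
                  FCONE FCONE);
  // dM = dZ %*% t(W) : (plane x Cout)(Cout x K)
  std::vector<double> dM(plane * K);
  F77_CALL(dgemm)("N", "T", &m, &K, &Cout, &one,
                  const_cast<double *>(dzp), &m, REAL(W), &K, &zero,
                  dM.data(), &m FCONE FCONE);
  std::fill(dX.begin(), dX.end(), 0.0);
  col2im_acc(dM.data(), B, H, Wd, Cin, dX.begin());

  dW.attr("dim") = IntegerVector::create(9, Cin, Cout);
  dX.attr("dim") = IntegerVector::create(B, H, Wd, Cin);
  return List::create(_["dW"] = dW, _["db"] = db, _["dX"] = dX);
}
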