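// Low-level 3D conv / pooling kernels used by the encoder.
//
// Tensor layout everywhere: a batch is a numeric array with
// dim = c(Z, Y, X, C, N); Z (slice index) varies fastest, matching the
// (slice, row, col) volume convention used on the R side.
//
// Convolutions are fixed 3x3x3, stride 1, zero padding 1 (VGG convention);
// the weight matrix is (Cout x Cin*27), column index c*27 + k with
// k = kz + 3*ky + 9*kx and kernel offsets kz,ky,kx in {0,1,2} (offset - 1).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

// Gather one sample (C x Z x Y x X, spatial-contiguous) into an (S x K)
// patch matrix, S = Z*Y*X output voxels, K = C*27.
void im2col3d(const double* x, int Z, int Y, int X, int C, arma::mat& cols) {
  const int S = Z * Y * X;
  cols.zeros();
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (std::size_t)c * S;
    for (int kx = 0; kx < 3; ++kx) {
      const int ox = kx - 1;
      for (int ky = 0; ky < 3; ++ky) {
        const int oy = ky - 1;
        for (int kz = 0; kz < 3; ++kz) {
          const int oz = kz - 1;
          double* dst = cols.colptr(c * 27 + kz + 3 * ky + 9 * kx);
          // copy x shifted by (oz,oy,ox) into dst; zeros elsewhere
          const int x0 = std::max(0, -ox), x1 = std::min(X, X - ox);
          const int y0 = std::max(0, -oy), y1 = std::min(Y, Y - oy);
          const int z0 = std::max(0, -oz), z1 = std::min(Z, Z - oz);
          if (z1 <= z0) continue;
          for (int xx = x0; xx < x1; ++xx) {
            for (int yy = y0; yy < y1; ++yy) {
              const std::size_t doff = (std::size_t)z0 + Z * (yy + (std::size_t)Y * xx);
              const std::size_t soff = (std::size_t)(z0 + oz) +
                Z * ((yy + oy) + (std::size_t)Y * (xx + ox));
              std::memcpy(dst + doff, xc + soff, sizeof(double) * (z1 - z0));
            }
          }
        }
      }
    }
  }
}

// Scatter-add transpose of im2col3d: dcols (S x K) -> dx (C x spatial).
void col2im3d(const arma::mat& dcols, int Z, int Y, int X, int C, double* dx) {
  const int S = Z * Y * X;
  for (int c = 0; c < C; ++c) {
    double* xc = dx + (std::size_t)c * S;
    for (int kx = 0; kx < 3; ++kx) {
      const int ox = kx - 1;
      for (int ky = 0; ky < 3; ++ky) {
        const int oy = ky - 1;
        for (int kz = 0; kz < 3; ++kz) {
          const int oz = kz - 1;
          const double* src = dcols.colptr(c * 27 + kz + 3 * ky + 9 * kx);
          const int x0 = std::max(0, -ox), x1 = std::min(X, X - ox);
          const int y0 = std::max(0, -oy), y1 = std::min(Y, Y - oy);
          const int z0 = std::max(0, -oz), z1 = std::min(Z, Z - oz);
          if (z1 <= z0) continue;
          for (int xx = x0; xx < x1; ++xx) {
            for (int yy = y0; yy < y1; ++yy) {
              const std::size_t doff = (std::size_t)(z0 + oz) +
                Z * ((yy + oy) + (std::size_t)Y * (xx + ox));
              const std::size_t soff = (std::size_t)z0 + Z * (yy + (std::size_t)Y * xx);
              double* d = xc + doff;
              const double* s = src + soff;
              for (int zz = 0; zz < z1 - z0; ++zz) d[zz] += s[zz];
            }
          }
        }
      }
    }
  }
}

IntegerVector tensor_dims(const NumericVector& x) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 5) stop("expected a 5-d (Z,Y,X,C,N) tensor");
  return d;
}

} // namespace

// [[Rcpp::export]]
NumericVector cpp_conv3d_fwd(NumericVector x, NumericMatrix w, NumericVector b) {
  IntegerVector d = tensor_dims(x);
  const int Z = d[0], Y = d[1], X = d[2], C = d[3], N = d[4];
  const int S = Z * Y * X, K = C * 27, Cout = w.nrow();
  if (w.ncol() != K) stop("weight shape mismatch: expected %d columns", K);
  arma::mat W(w.begin(), Cout, K, false, true);
  arma::vec bv(b.begin(), Cout, false, true);
  NumericVector out((std::size_t)S * Cout * N);
  out.attr("dim") = IntegerVector::create(Z, Y, X, Cout, N);
  arma::mat cols(S, K);
  for (int n = 0; n < N; ++n) {
    im2col3d(x.begin() + (std::size_t)n * S * C, Z, Y, X, C, cols);
    arma::mat yview(out.begin() + (std::size_t)n * S * Cout, S, Cout, false, true);
    yview = cols * W.t();
    yview.each_row() += bv.t();
  }
  return out;
}

// [[Rcpp::export]]
List cpp_conv3d_bwd(NumericVector x, NumericMatrix w, NumericVector dy) {
  IntegerVector d = tensor_dims(x);
  const int Z = d[0], Y = d[1], X = d[2], C = d[3], N = d[4];
  const int S = Z * Y * X, K = C * 27, Cout = w.nrow();
  arma::mat W(w.begin(), Cout, K, false, true);
  NumericVector dx(x.size());
  dx.attr("dim") = d;
  arma::mat dW(Cout, K, arma::fill::zeros);
  arma::vec db(Cout, arma::fill::zeros);
  arma::mat cols(S, K), dcols(S, K);
  for (int n = 0; n < N; ++n) {
    im2col3d(x.begin() + (std::size_t)n * S * C, Z, Y, X, C, cols);
    arma::mat dyv((double*)dy.begin() + (std::size_t)n * S * Cout, S, Cout, false, true);
    dW += dyv.t() * cols;
    db += arma::sum(dyv, 0).t();
    dcols = dyv * W;
    col2im3d(dcols, Z, Y, X, C, dx.begin() + (std::size_t)n * S * C);
  }
  return List::create(_["dx"] = dx, _["dw"] = wrap(dW), _["db"] = wrap(db));
}

// 2x2x2 max pooling, stride 2, ceil mode. Returns pooled tensor plus the
// 1-based linear argmax indices into the input (for the backward pass).
// [[Rcpp::export]]
List cpp_maxpool3d_fwd(NumericVector x) {
  IntegerVector d = tensor_dims(x);
  const int Z = d[0], Y = d[1], X = d[2], C = d[3], N = d[4];
  const int Zo = (Z + 1) / 2, Yo = (Y + 1) / 2, Xo = (X + 1) / 2;
  const std::size_t So = (std::size_t)Zo * Yo * Xo, nslab = (std::size_t)C * N;
  NumericVector out(So * nslab);
  out.attr("dim") = IntegerVector::create(Zo, Yo, Xo, C, N);
  NumericVector idx(So * nslab); // double to allow > 2^31 offsets
  const std::size_t S = (std::size_t)Z * Y * X;
  for (std::size_t s = 0; s < nslab; ++s) {
    const double* xs = x.begin() + s * S;
    double* os = out.begin() + s * So;
    double* is = idx.begin() + s * So;
    for (int xo = 0; xo < Xo; ++xo)
      for (int yo = 0; yo < Yo; ++yo)
        for (int zo = 0; zo < Zo; ++zo) {
          double best = -std::numeric_limits<double>::infinity();
          std::size_t besti = 0;
          for (int dxp = 0; dxp < 2; ++dxp) {
            int xi = 2 * xo + dxp; if (xi >= X) continue;
            for (int dyp = 0; dyp < 2; ++dyp) {
              int yi = 2 * yo + dyp; if (yi >= Y) continue;
              for (int dzp = 0; dzp < 2; ++dzp) {
                int zi = 2 * zo + dzp; if (zi >= Z) continue;
                std::size_t li = (std::size_t)zi + Z * (yi + (std::size_t)Y * xi);
                if (xs[li] > best) { best = xs[li]; besti = li; }
              }
            }
          }
          std::size_t lo = (std::size_t)zo + Zo * (yo + (std::size_t)Yo * xo);
          os[lo] = best;
          is[lo] = (double)(s * S + besti + 1);
        }
  }
  return List::create(_["y"] = out, _["argmax"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool3d_bwd(NumericVector argmax, NumericVector dy,
                                IntegerVector xdim) {
  std::size_t n = 1;
  for (int i = 0; i < xdim.size(); ++i) n *= (std::size_t)xdim[i];
  NumericVector dx(n);
  dx.attr("dim") = xdim;
  for (R_xlen_t i = 0; i < dy.size(); ++i)
    dx[(std::size_t)argmax[i] - 1] += dy[i];
  return dx;
}
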