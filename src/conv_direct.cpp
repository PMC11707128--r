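// Direct cache-blocked 3x3x3 convolution kernels (same padding). The im2col
// route materializes a 27x blown-up patch matrix, which dominated runtime on
// a single core; these kernels instead sweep z-slices and accumulate all
// output channels in one pass over the input, keeping the working set in
// cache. Weight layout matches the R side: W is a (27*Cin) x Cout matrix
// with row index o*Cin + ci, offsets o enumerated dz-major (dz, dy, dx in
// -1..1, dx fastest). Feature maps are N x C column-major (x fastest).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline size_t sl(int j, int k, int nx, int ny) {
  return (size_t)nx * ((size_t)j + (size_t)ny * (size_t)k);
}

// [[Rcpp::export(name = ".cs_conv_fwd_direct")]]
arma::mat cs_conv_fwd_direct(const arma::mat& X, const IntegerVector& dims,
                             const arma::mat& W, const arma::rowvec& b) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int Cin = X.n_cols, Cout = W.n_cols;
  const size_t N = (size_t)nx * ny * nz;
  const size_t slab = (size_t)nx * ny;
  arma::mat Y(N, Cout);
  std::vector<double> acc(slab * Cout);
  for (int k = 0; k < nz; ++k) {
    for (int co = 0; co < Cout; ++co)
      std::fill(acc.begin() + co * slab, acc.begin() + (co + 1) * slab, b[co]);
    int o = 0;
    for (int dz = -1; dz <= 1; ++dz) {
      const int sk = k + dz;
      if (sk < 0 || sk >= nz) { o += 9; continue; }
      for (int dy = -1; dy <= 1; ++dy) {
        for (int dx = -1; dx <= 1; ++dx, ++o) {
          const int i0 = std::max(0, -dx), i1 = std::min(nx - 1, nx - 1 - dx);
          const int len = i1 - i0 + 1;
          if (len <= 0) continue;
          for (int ci = 0; ci < Cin; ++ci) {
            const double* xs = X.colptr(ci);
            for (int j = 0; j < ny; ++j) {
              const int sj = j + dy;
              if (sj < 0 || sj >= ny) continue;
              const double* __restrict s = xs + sl(sj, sk, nx, ny) + i0 + dx;
              const size_t row = (size_t)nx * j + i0;
              // accumulate every output channel from this input row
              for (int co = 0; co < Cout; ++co) {
                const double w = W(o * Cin + ci, co);
                if (w == 0.0) continue;
                double* __restrict a = acc.data() + co * slab + row;
                for (int t = 0; t < len; ++t) a[t] += w * s[t];
              }
            }
          }
        }
      }
    }
    for (int co = 0; co < Cout; ++co)
      std::memcpy(Y.colptr(co) + sl(0, k, nx, ny), acc.data() + co * slab,
                  sizeof(double) * slab);
  }
  return Y;
}

// [[Rcpp::export(name = ".cs_conv_bwd_direct")]]
List cs_conv_bwd_direct(const arma::mat& X, const IntegerVector& dims,
                        const arma::mat& W, const arma::mat& dY, bool need_dx) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int Cin = X.n_cols, Cout = W.n_cols;
  const size_t slab = (size_t)nx * ny;
  arma::mat dW(27 * (size_t)Cin, Cout, arma::fill::zeros);
  arma::rowvec db = arma::sum(dY, 0);
  // dW[o*Cin+ci, co] = sum_n X[n + shift(o), ci] * dY[n, co]
  for (int k = 0; k < nz; ++k) {
    int o = 0;
    for (int dz = -1; dz <= 1; ++dz) {
      const int sk = k + dz;
      if (sk < 0 || sk >= nz) { o += 9; continue; }
      for (int dy = -1; dy <= 1; ++dy) {
        for (int dx = -1; dx <= 1; ++dx, ++o) {
          const int i0 = std::max(0, -dx), i1 = std::min(nx - 1, nx - 1 - dx);
          const int len = i1 - i0 + 1;
          if (len <= 0) continue;
          for (int ci = 0; ci < Cin; ++ci) {
            const double* xs = X.colptr(ci);
            for (int j = 0; j < ny; ++j) {
              const int sj = j + dy;
              if (sj < 0 || sj >= ny) continue;
              const double* __restrict xp = xs + sl(sj, sk, nx, ny) + i0 + dx;
              const size_t row = sl(j, k, nx, ny) + i0;
              for (int co = 0; co < Cout; ++co) {
                const double* __restrict g = dY.colptr(co) + row;
                double a0 = 0.0, a1 = 0.0, a2 = 0.0, a3 = 0.0;
                int t = 0;
                for (; t + 3 < len; t += 4) {
                  a0 += g[t] * xp[t]; a1 += g[t + 1] * xp[t + 1];
                  a2 += g[t + 2] * xp[t + 2]; a3 += g[t + 3] * xp[t + 3];
                }
                for (; t < len; ++t) a0 += g[t] * xp[t];
                dW(o * Cin + ci, co) += (a0 + a1) + (a2 + a3);
              }
            }
          }
        }
      }
    }
  }
  if (!need_dx) return List::create(_["dW"] = dW, _["db"] = db);
  // dX[m, ci] = sum_{o, co} W[o*Cin+ci, co] * dY[m - shift(o), co]
  arma::mat dX(X.n_rows, Cin);
  std::vector<double> acc(slab * Cin);
  for (int k = 0; k < nz; ++k) {
    std::fill(acc.begin(), acc.end(), 0.0);
    int o = 0;
    for (int dz = -1; dz <= 1; ++dz) {
      const int gk = k - dz;
      if (gk < 0 || gk >= nz) { o += 9; continue; }
      for (int dy = -1; dy <= 1; ++dy) {
        for (int dx = -1; dx <= 1; ++dx, ++o) {
          const int i0 = std::max(0, dx), i1 = std::min(nx - 1, nx - 1 + dx);
          const int len = i1 - i0 + 1;
          if (len <= 0) continue;
          for (int co = 0; co < Cout; ++co) {
            const double* gc = dY.colptr(co);
            for (int j = 0; j < ny; ++j) {
              const int gj = j - dy;
              if (gj < 0 || gj >= ny) continue;
              const double* __restrict g = gc + sl(gj, gk, nx, ny) + i0 - dx;
              const size_t row = (size_t)nx * j + i0;
              for (int ci = 0; ci < Cin; ++ci) {
                const double w = W(o * Cin + ci, co);
                if (w == 0.0) continue;
                double* __restrict a = acc.data() + ci * slab + row;
                for (int t = 0; t < len; ++t) a[t] += w * g[t];
              }
            }
          }
        }
      }
    }
    for (int ci = 0; ci < Cin; ++ci)
      std::memcpy(dX.colptr(ci) + sl(0, k, nx, ny), acc.data() + ci * slab,
                  sizeof(double) * slab);
  }
  return List::create(_["dW"] = dW, _["db"] = db, _["dX"] = dX);
}
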