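// Dense 3D network primitives: im2col-based 3x3x3 convolution (same padding),
// 2x2x2 max pooling, nearest-neighbour upsampling, and trilinear/nearest grid
// resampling. Feature maps are N x C matrices, N = nx*ny*nz voxels in R's
// column-major order (x fastest), one column per channel.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline arma::uword vox(int i, int j, int k, int nx, int ny) {
  return (arma::uword)i + (arma::uword)nx * ((arma::uword)j + (arma::uword)ny * (arma::uword)k);
}

// K[n, o*C + c] = X[n + shift(o), c] with zero padding outside the grid.
static arma::mat im2col3(const arma::mat& X, int nx, int ny, int nz) {
  const int C = X.n_cols;
  const arma::uword N = X.n_rows;
  arma::mat K(N, 27 * (arma::uword)C, arma::fill::zeros);
  int o = 0;
  for (int dz = -1; dz <= 1; ++dz) {
    for (int dy = -1; dy <= 1; ++dy) {
      for (int dx = -1; dx <= 1; ++dx, ++o) {
        const int i0 = std::max(0, -dx), i1 = std::min(nx - 1, nx - 1 - dx);
        const int len = i1 - i0 + 1;
        if (len <= 0) continue;
        for (int c = 0; c < C; ++c) {
          const double* src = X.colptr(c);
          double* dst = K.colptr((arma::uword)o * C + c);
          for (int k = 0; k < nz; ++k) {
            const int sk = k + dz;
            if (sk < 0 || sk >= nz) continue;
            for (int j = 0; j < ny; ++j) {
              const int sj = j + dy;
              if (sj < 0 || sj >= ny) continue;
              std::memcpy(dst + vox(i0, j, k, nx, ny),
                          src + vox(i0 + dx, sj, sk, nx, ny),
                          sizeof(double) * (size_t)len);
            }
          }
        }
      }
    }
  }
  return K;
}

// Adjoint of im2col: dX[m, c] += G[m - shift(o), o*C + c].
static arma::mat col2im3(const arma::mat& G, int nx, int ny, int nz, int C) {
  const arma::uword N = G.n_rows;
  arma::mat dX(N, C, arma::fill::zeros);
  int o = 0;
  for (int dz = -1; dz <= 1; ++dz) {
    for (int dy = -1; dy <= 1; ++dy) {
      for (int dx = -1; dx <= 1; ++dx, ++o) {
        const int i0 = std::max(0, -dx), i1 = std::min(nx - 1, nx - 1 - dx);
        const int len = i1 - i0 + 1;
        if (len <= 0) continue;
        for (int c = 0; c < C; ++c) {
          const double* src = G.colptr((arma::uword)o * C + c);
          double* dst = dX.colptr(c);
          for (int k = 0; k < nz; ++k) {
            const int sk = k + dz;
            if (sk < 0 || sk >= nz) continue;
            for (int j = 0; j < ny; ++j) {
              const int sj = j + dy;
              if (sj < 0 || sj >= ny) continue;
              double* d = dst + vox(i0 + dx, sj, sk, nx, ny);
              const double* s = src + vox(i0, j, k, nx, ny);
              for (int t = 0; t < len; ++t) d[t] += s[t];
            }
          }
        }
      }
    }
  }
  return dX;
}

// [[Rcpp::export(name = ".cs_conv_fwd")]]
arma::mat cs_conv_fwd(const arma::mat& X, const IntegerVector& dims,
                      const arma::mat& W, const arma::rowvec& b) {
  arma::mat K = im2col3(X, dims[0], dims[1], dims[2]);
  arma::mat Y = K * W;
  Y.each_row() += b;
  return Y;
}

// [[Rcpp::export(name = ".cs_conv_bwd")]]
List cs_conv_bwd(const arma::mat& X, const IntegerVector& dims,
                 const arma::mat& W, const arma::mat& dY, bool need_dx) {
  arma::mat K = im2col3(X, dims[0], dims[1], dims[2]);
  arma::mat dW = K.t() * dY;
  arma::rowvec db = arma::sum(dY, 0);
  if (!need_dx) return List::create(_["dW"] = dW, _["db"] = db);
  arma::mat G = dY * W.t();
  arma::mat dX = col2im3(G, dims[0], dims[1], dims[2], X.n_cols);
  return List::create(_["dW"] = dW, _["db"] = db, _["dX"] = dX);
}

// 1x1x1 convolution is a plain matrix product; kept in R.

// [[Rcpp::export(name = ".cs_maxpool_fwd")]]
List cs_maxpool_fwd(const arma::mat& X, const IntegerVector& dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int mx = nx / 2, my = ny / 2, mz = nz / 2;
  const int C = X.n_cols;
  const arma::uword M = (arma::uword)mx * my * mz;
  arma::mat Y(M, C);
  arma::umat amax(M, C);
  for (int c = 0; c < C; ++c) {
    const double* src = X.colptr(c);
    for (int k = 0; k < mz; ++k)
      for (int j = 0; j < my; ++j)
        for (int i = 0; i < mx; ++i) {
          double best = -std::numeric_limits<double>::infinity();
          arma::uword arg = 0;
          for (int dk = 0; dk < 2; ++dk)
            for (int dj = 0; dj < 2; ++dj)
              for (int di = 0; di < 2; ++di) {
                arma::uword s = vox(2 * i + di, 2 * j + dj, 2 * k + dk, nx, ny);
                if (src[s] > best) { best = src[s]; arg = s; }
              }
          arma::uword m = vox(i, j, k, mx, my);
          Y(m, c) = best;
          amax(m, c) = arg;
        }
  }
  return List::create(_["Y"] = Y, _["amax"] = amax);
}

// [[Rcpp::export(name = ".cs_maxpool_bwd")]]
arma::mat cs_maxpool_bwd(const arma::mat& dY, const arma::umat& amax, int N) {
  arma::mat dX((arma::uword)N, dY.n_cols, arma::fill::zeros);
  for (arma::uword c = 0; c < dY.n_cols; ++c)
    for (arma::uword m = 0; m < dY.n_rows; ++m)
      dX(amax(m, c), c) += dY(m, c);
  return dX;
}

// [[Rcpp::export(name = ".cs_upsample_fwd")]]
arma::mat cs_upsample_fwd(const arma::mat& X, const IntegerVector& dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int ox = 2 * nx, oy = 2 * ny, oz = 2 * nz;
  arma::mat Y((arma::uword)ox * oy * oz, X.n_cols);
  for (arma::uword c = 0; c < X.n_cols; ++c) {
    const double* src = X.colptr(c);
    double* dst = Y.colptr(c);
    for (int k = 0; k < oz; ++k)
      for (int j = 0; j < oy; ++j) {
        const double* srow = src + vox(0, j / 2, k / 2, nx, ny);
        double* drow = dst + vox(0, j, k, ox, oy);
        for (int i = 0; i < ox; ++i) drow[i] = srow[i / 2];
      }
  }
  return Y;
}

// [[Rcpp::export(name = ".cs_upsample_bwd")]]
arma::mat cs_upsample_bwd(const arma::mat& dY, const IntegerVector& dims_in) {
  const int nx = dims_in[0], ny = dims_in[1], nz = dims_in[2];
  const int ox = 2 * nx, oy = 2 * ny;
  arma::mat dX((arma::uword)nx * ny * dims_in[2], dY.n_cols, arma::fill::zeros);
  for (arma::uword c = 0; c < dY.n_cols; ++c) {
    const double* src = dY.colptr(c);
    double* dst = dX.colptr(c);
    for (int k = 0; k < 2 * dims_in[2]; ++k)
      for (int j = 0; j < oy; ++j) {
        const double* srow = src + vox(0, j, k, ox, oy);
        double* drow = dst + vox(0, j / 2, k / 2, nx, ny);
        for (int i = 0; i < ox; ++i) drow[i / 2] += srow[i];
      }
  }
  return dX;
}

// Grid resampling between two cell-centred geometries, mm coordinates.
// [[Rcpp::export(name = ".cs_resample")]]
NumericVector cs_resample(const NumericVector& src, const IntegerVector& din,
                          const NumericVector& sin_, const NumericVector& oin,
                          const IntegerVector& dout, const NumericVector& sout,
                          const NumericVector& oout, bool nearest) {
  const int nx = din[0], ny = din[1], nz = din[2];
  const int ox = dout[0], oy = dout[1], oz = dout[2];
  NumericVector out((R_xlen_t)ox * oy * oz);
  const double* s = src.begin();
  double* d = out.begin();
  for (int k = 0; k < oz; ++k) {
    double w = (oout[2] + k * sout[2] - oin[2]) / sin_[2];
    for (int j = 0; j < oy; ++j) {
      double v = (oout[1] + j * sout[1] - oin[1]) / sin_[1];
      for (int i = 0; i < ox; ++i) {
        double u = (oout[0] + i * sout[0] - oin[0]) / sin_[0];
        double uu = std::min(std::max(u, 0.0), (double)(nx - 1));
        double vv = std::min(std::max(v, 0.0), (double)(ny - 1));
        double ww = std::min(std::max(w, 0.0), (double)(nz - 1));
        double val;
        if (nearest) {
          int i0 = (int)std::lround(uu), j0 = (int)std::lround(vv), k0 = (int)std::lround(ww);
          val = s[vox(i0, j0, k0, nx, ny)];
        } else {
          int i0 = std::min((int)uu, nx - 2 >= 0 ? nx - 2 : 0);
          int j0 = std::min((int)vv, ny - 2 >= 0 ? ny - 2 : 0);
          int k0 = std::min((int)ww, nz - 2 >= 0 ? nz - 2 : 0);
          if (nx == 1) i0 = 0;
          if (ny == 1) j0 = 0;
          if (nz == 1) k0 = 0;
          double fx = uu - i0, fy = vv - j0, fz = ww - k0;
          int i1 = std::min(i0 + 1, nx - 1), j1 = std::min(j0 + 1, ny - 1), k1 = std::min(k0 + 1, nz - 1);
          double c000 = s[vox(i0, j0, k0, nx, ny)], c100 = s[vox(i1, j0, k0, nx, ny)];
          double c010 = s[vox(i0, j1, k0, nx, ny)], c110 = s[vox(i1, j1, k0, nx, ny)];
          double c001 = s[vox(i0, j0, k1, nx, ny)], c101 = s[vox(i1, j0, k1, nx, ny)];
          double c011 = s[vox(i0, j1, k1, nx, ny)], c111 = s[vox(i1, j1, k1, nx, ny)];
          double c00 = c000 + fx * (c100 - c000), c10 = c010 + fx * (c110 - c010);
          double c01 = c001 + fx * (c101 - c001), c11 = c011 + fx * (c111 - c011);
          double c0 = c00 + fy * (c10 - c00), c1 = c01 + fy * (c11 - c01);
          val = c0 + fz * (c1 - c0);
        }
        d[vox(i, j, k, ox, oy)] = val;
      }
    }
  }
  return out;
}
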