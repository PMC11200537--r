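// Compute kernels for the segmentation network and its evaluation suite.
// Feature maps are passed as flat numeric vectors in channel-first,
// column-major layout: index = c + C*(x + X*(y + Y*z)).

#include <RcppArmadillo.h>
#include <queue>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// ---------------------------------------------------------------------------
// Dense 3D convolution (cross-correlation) via im2col + GEMM.
// Weights: Cout x (Cin*kx*ky*kz), column r = c + Cin*(i + kx*(j + ky*l)).
// ---------------------------------------------------------------------------

static void im2col(const double* x, int C, int X, int Y, int Z,
                   int kx, int ky, int kz, int sx, int sy, int sz,
                   int px, int py, int pz, int Xo, int Yo, int Zo,
                   arma::mat& cols) {
  const int rows = C * kx * ky * kz;
  for (int oz = 0; oz < Zo; ++oz)
    for (int oy = 0; oy < Yo; ++oy)
      for (int ox = 0; ox < Xo; ++ox) {
        const arma::uword q = (arma::uword)ox + (arma::uword)Xo * (oy + (arma::uword)Yo * oz);
        double* col = cols.colptr(q);
        int r = 0;
        for (int l = 0; l < kz; ++l) {
          int iz = oz * sz - pz + l;
          for (int j = 0; j < ky; ++j) {
            int iy = oy * sy - py + j;
            for (int i = 0; i < kx; ++i) {
              int ix = ox * sx - px + i;
              if (ix < 0 || ix >= X || iy < 0 || iy >= Y || iz < 0 || iz >= Z) {
                for (int c = 0; c < C; ++c) col[r++] = 0.0;
              } else {
                const double* src = x + (size_t)C * (ix + (size_t)X * (iy + (size_t)Y * iz));
                for (int c = 0; c < C; ++c) col[r++] = src[c];
              }
            }
          }
        }
        (void)rows;
      }
}

static void col2im(const arma::mat& cols, double* dx, int C, int X, int Y, int Z,
                   int kx, int ky, int kz, int sx, int sy, int sz,
                   int px, int py, int pz, int Xo, int Yo, int Zo) {
  for (int oz = 0; oz < Zo; ++oz)
    for (int oy = 0; oy < Yo; ++oy)
      for (int ox = 0; ox < Xo; ++ox) {
        const arma::uword q = (arma::uword)ox + (arma::uword)Xo * (oy + (arma::uword)Yo * oz);
        const double* col = cols.colptr(q);
        int r = 0;
        for (int l = 0; l < kz; ++l) {
          int iz = oz * sz - pz + l;
          for (int j = 0; j < ky; ++j) {
            int iy = oy * sy - py + j;
            for (int i = 0; i < kx; ++i) {
              int ix = ox * sx - px + i;
              if (ix < 0 || ix >= X || iy < 0 || iy >= Y || iz < 0 || iz >= Z) {
                r += C;
              } else {
                double* dst = dx + (size_t)C * (ix + (size_t)X * (iy + (size_t)Y * iz));
                for (int c = 0; c < C; ++c) dst[c] += col[r++];
              }
            }
          }
        }
      }
}

// [[Rcpp::export]]
NumericVector cpp_conv3d_fw(NumericVector x, IntegerVector dims,
                            const arma::mat& w, NumericVector b,
                            IntegerVector k, IntegerVector stride,
                            IntegerVector pad) {
  const int C = dims[0], X = dims[1], Y = dims[2], Z = dims[3];
  const int kx = k[0], ky = k[1], kz = k[2];
  const int sx = stride[0], sy = stride[1], sz = stride[2];
  const int px = pad[0], py = pad[1], pz = pad[2];
  const int Xo = (X + 2 * px - kx) / sx + 1;
  const int Yo = (Y + 2 * py - ky) / sy + 1;
  const int Zo = (Z + 2 * pz - kz) / sz + 1;
  const int Cout = w.n_rows;
  const arma::uword N = (arma::uword)Xo * Yo * Zo;

  arma::mat cols(w.n_cols, N);
  im2col(REAL(x), C, X, Y, Z, kx, ky, kz, sx, sy, sz, px, py, pz, Xo, Yo, Zo, cols);
  arma::mat ymat = w * cols;
  NumericVector y((R_xlen_t)Cout * N);
  double* yp = REAL(y);
  const double* bp = REAL(b);
  for (arma::uword q = 0; q < N; ++q) {
    const double* src = ymat.colptr(q);
    double* dst = yp + (size_t)Cout * q;
    for (int c = 0; c < Cout; ++c) dst[c] = src[c] + bp[c];
  }
  y.attr("odims") = IntegerVector::create(Cout, Xo, Yo, Zo);
  return y;
}

// [[Rcpp::export]]
List cpp_conv3d_bw(NumericVector x, IntegerVector dims,
                   const arma::mat& w, NumericVector dy, IntegerVector ydims,
                   IntegerVector k, IntegerVector stride, IntegerVector pad) {
  const int C = dims[0], X = dims[1], Y = dims[2], Z = dims[3];
  const int kx = k[0], ky = k[1], kz = k[2];
  const int sx = stride[0], sy = stride[1], sz = stride[2];
  const int px = pad[0], py = pad[1], pz = pad[2];
  const int Cout = ydims[0], Xo = ydims[1], Yo = ydims[2], Zo = ydims[3];
  const arma::uword N = (arma::uword)Xo * Yo * Zo;

  arma::mat dymat(REAL(dy), Cout, N, false, true);
  arma::mat cols(w.n_cols, N);
  im2col(REAL(x), C, X, Y, Z, kx, ky, kz, sx, sy, sz, px, py, pz, Xo, Yo, Zo, cols);

  arma::mat dw = dymat * cols.t();
  arma::vec db = arma::sum(dymat, 1);
  arma::mat gcols = w.t() * dymat;

  NumericVector dx((R_xlen_t)C * X * Y * Z);  // zero-initialised
  col2im(gcols, REAL(dx), C, X, Y, Z, kx, ky, kz, sx, sy, sz, px, py, pz, Xo, Yo, Zo);
  return List::create(_["dx"] = dx, _["dw"] = dw,
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// ---------------------------------------------------------------------------
// Transposed convolution, kernel 2, stride 2 (learned 2x upsampling).
// Weights: (Cout*8) x Cin, row = co + Cout*(i + 2*(j + 2*l)).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_deconv2_fw(NumericVector x, IntegerVector dims,
                             const arma::mat& w, NumericVector b) {
  const int C = dims[0], X = dims[1], Y = dims[2], Z = dims[3];
  const int Cout = w.n_rows / 8;
  const arma::uword N = (arma::uword)X * Y * Z;
  arma::mat xmat(REAL(x), C, N, false, true);
  arma::mat ymat = w * xmat;  // (Cout*8) x N
  const int Xo = 2 * X, Yo = 2 * Y, Zo = 2 * Z;
  NumericVector y((R_xlen_t)Cout * Xo * Yo * Zo);
  double* yp = REAL(y);
  const double* bp = REAL(b);
  for (R_xlen_t v = 0; v < y.size(); ++v) yp[v] = bp[v % Cout];
  for (int z = 0; z < Z; ++z)
    for (int yy = 0; yy < Y; ++yy)
      for (int xx = 0; xx < X; ++xx) {
        const arma::uword q = (arma::uword)xx + (arma::uword)X * (yy + (arma::uword)Y * z);
        const double* src = ymat.colptr(q);
        for (int l = 0; l < 2; ++l)
          for (int j = 0; j < 2; ++j)
            for (int i = 0; i < 2; ++i) {
              double* dst = yp + (size_t)Cout *
                ((2 * xx + i) + (size_t)Xo * ((2 * yy + j) + (size_t)Yo * (2 * z + l)));
              const double* s = src + (size_t)Cout * (i + 2 * (j + 2 * l));
              for (int c = 0; c < Cout; ++c) dst[c] += s[c];
            }
      }
  y.attr("odims") = IntegerVector::create(Cout, Xo, Yo, Zo);
  return y;
}

// [[Rcpp::export]]
List cpp_deconv2_bw(NumericVector x, IntegerVector dims,
                    const arma::mat& w, NumericVector dy) {
  const int C = dims[0], X = dims[1], Y = dims[2], Z = dims[3];
  const int Cout = w.n_rows / 8;
  const arma::uword N = (arma::uword)X * Y * Z;
  const int Xo = 2 * X, Yo = 2 * Y, Zo = 2 * Z;
  arma::mat dyg(Cout * 8, N);  // gathered
  const double* dyp = REAL(dy);
  arma::vec db(Cout, arma::fill::zeros);
  for (int z = 0; z < Z; ++z)
    for (int yy = 0; yy < Y; ++yy)
      for (int xx = 0; xx < X; ++xx) {
        const arma::uword q = (arma::uword)xx + (arma::uword)X * (yy + (arma::uword)Y * z);
        double* dst = dyg.colptr(q);
        for (int l = 0; l < 2; ++l)
          for (int j = 0; j < 2; ++j)
            for (int i = 0; i < 2; ++i) {
              const double* s = dyp + (size_t)Cout *
                ((2 * xx + i) + (size_t)Xo * ((2 * yy + j) + (size_t)Yo * (2 * z + l)));
              double* d = dst + (size_t)Cout * (i + 2 * (j + 2 * l));
              for (int c = 0; c < Cout; ++c) { d[c] = s[c]; db[c] += s[c]; }
            }
      }
  arma::mat xmat(REAL(x), C, N, false, true);
  arma::mat dw = dyg * xmat.t();
  arma::mat dxm = w.t() * dyg;
  NumericVector dx((R_xlen_t)C * N);
  std::memcpy(REAL(dx), dxm.memptr(), sizeof(double) * C * N);
  return List::create(_["dx"] = dx, _["dw"] = dw,
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// ---------------------------------------------------------------------------
// Depth-wise convolution, arbitrary odd kernel, same (zero) padding, no bias.
// Weights: C x (kx*ky*kz), column t = i + kx*(j + ky*l).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_depthwise_fw(NumericVector x, IntegerVector dims,
                               const arma::mat& w, IntegerVector k) {
  const int C = dims[0], X = dims[1], Y = dims[2], Z = dims[3];
  const int kx = k[0], ky = k[1], kz = k[2];
  const int px = kx / 2, py = ky / 2, pz = kz / 2;
  NumericVector y((R_xlen_t)C * X * Y * Z);
  const double* xp = REAL(x);
  double* yp = REAL(y);
  for (int z = 0; z < Z; ++z)
    for (int yy = 0; yy < Y; ++yy)
      for (int xx = 0; xx < X; ++xx) {
        double* dst = yp + (size_t)C * (xx + (size_t)X * (yy + (size_t)Y * z));
        for (int l = 0; l < kz; ++l) {
          int iz = z - pz + l;
          if (iz < 0 || iz >= Z) continue;
          for (int j = 0; j < ky; ++j) {
            int iy = yy - py + j;
            if (iy < 0 || iy >= Y) continue;
            for (int i = 0; i < kx; ++i) {
              int ix = xx - px + i;
              if (ix < 0 || ix >= X) continue;
              const double* src = xp + (size_t)C * (ix + (size_t)X * (iy + (size_t)Y * iz));
              const int t = i + kx * (j + ky * l);
              for (int c = 0; c < C; ++c) dst[c] += w(c, t) * src[c];
            }
          }
        }
      }
  return y;
}

// [[Rcpp::export]]
List cpp_depthwise_bw(NumericVector x, IntegerVector dims,
                      const arma::mat& w, NumericVector dy, IntegerVector k) {
  const int C = dims[0], X = dims[1], Y = dims[2], Z = dims[3];
  const int kx = k[0], ky = k[1], kz = k[2];
  const int px = kx / 2, py = ky / 2, pz = kz / 2;
  NumericVector dx((R_xlen_t)C * X * Y * Z);
  arma::mat dw(C, kx * ky * kz, arma::fill::zeros);
  const double* xp = REAL(x);
  const double* dyp = REAL(dy);
  double* dxp = REAL(dx);
  for (int z = 0; z < Z; ++z)
    for (int yy = 0; yy < Y; ++yy)
      for (int xx = 0; xx < X; ++xx) {
        const double* g = dyp + (size_t)C * (xx + (size_t)X * (yy + (size_t)Y * z));
        for (int l = 0; l < kz; ++l) {
          int iz = z - pz + l;
          if (iz < 0 || iz >= Z) continue;
          for (int j = 0; j < ky; ++j) {
            int iy = yy - py + j;
            if (iy < 0 || iy >= Y) continue;
            for (int i = 0; i < kx; ++i) {
              int ix = xx - px + i;
              if (ix < 0 || ix >= X) continue;
              const size_t off = (size_t)C * (ix + (size_t)X * (iy + (size_t)Y * iz));
              const int t = i + kx * (j + ky * l);
              for (int c = 0; c < C; ++c) {
                dxp[off + c] += w(c, t) * g[c];
                dw(c, t) += xp[off + c] * g[c];
              }
            }
          }
        }
      }
  return List::create(_["dx"] = dx, _["dw"] = dw);
}

// ---------------------------------------------------------------------------
// Trilinear resize (half-pixel centre alignment) and its adjoint.
// ---------------------------------------------------------------------------

static void lin_coeffs(int No, int Ni, std::vector<int>& i0, std::vector<int>& i1,
                       std::vector<double>& w1) {
  i0.resize(No); i1.resize(No); w1.resize(No);
  const double f = (double)Ni / No;
  for (int o = 0; o < No; ++o) {
    double s = (o + 0.5) * f - 0.5;
    if (s < 0) s = 0;
    if (s > Ni - 1) s = Ni - 1;
    int a = (int)std::floor(s);
    int b = std::min(a + 1, Ni - 1);
    i0[o] = a; i1[o] = b; w1[o] = s - a;
  }
}

// [[Rcpp::export]]
NumericVector cpp_resize_trilinear_fw(NumericVector x, IntegerVector dims,
                                      IntegerVector odims) {
  const int C = dims[0], X = dims[1], Y = dims[2], Z = dims[3];
  const int Xo = odims[0], Yo = odims[1], Zo = odims[2];
  std::vector<int> x0, x1, y0, y1, z0, z1;
  std::vector<double> wx, wy, wz;
  lin_coeffs(Xo, X, x0, x1, wx);
  lin_coeffs(Yo, Y, y0, y1, wy);
  lin_coeffs(Zo, Z, z0, z1, wz);
  NumericVector y((R_xlen_t)C * Xo * Yo * Zo);
  const double* xp = REAL(x);
  double* yp = REAL(y);
  for (int oz = 0; oz < Zo; ++oz)
    for (int oy = 0; oy < Yo; ++oy)
      for (int ox = 0; ox < Xo; ++ox) {
        double* dst = yp + (size_t)C * (ox + (size_t)Xo * (oy + (size_t)Yo * oz));
        for (int dz = 0; dz < 2; ++dz)
          for (int dyi = 0; dyi < 2; ++dyi)
            for (int dxi = 0; dxi < 2; ++dxi) {
              const double wgt = (dxi ? wx[ox] : 1 - wx[ox]) *
                                 (dyi ? wy[oy] : 1 - wy[oy]) *
                                 (dz ? wz[oz] : 1 - wz[oz]);
              if (wgt == 0) continue;
              const int ix = dxi ? x1[ox] : x0[ox];
              const int iy = dyi ? y1[oy] : y0[oy];
              const int iz = dz ? z1[oz] : z0[oz];
              const double* src = xp + (size_t)C * (ix + (size_t)X * (iy + (size_t)Y * iz));
              for (int c = 0; c < C; ++c) dst[c] += wgt * src[c];
            }
      }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_resize_trilinear_bw(NumericVector dy, IntegerVector odims4,
                                      IntegerVector idims4) {
  const int C = odims4[0], Xo = odims4[1], Yo = odims4[2], Zo = odims4[3];
  const int X = idims4[1], Y = idims4[2], Z = idims4[3];
  std::vector<int> x0, x1, y0, y1, z0, z1;
  std::vector<double> wx, wy, wz;
  lin_coeffs(Xo, X, x0, x1, wx);
  lin_coeffs(Yo, Y, y0, y1, wy);
  lin_coeffs(Zo, Z, z0, z1, wz);
  NumericVector dx((R_xlen_t)C * X * Y * Z);
  const double* dyp = REAL(dy);
  double* dxp = REAL(dx);
  for (int oz = 0; oz < Zo; ++oz)
    for (int oy = 0; oy < Yo; ++oy)
      for (int ox = 0; ox < Xo; ++ox) {
        const double* g = dyp + (size_t)C * (ox + (size_t)Xo * (oy + (size_t)Yo * oz));
        for (int dz = 0; dz < 2; ++dz)
          for (int dyi = 0; dyi < 2; ++dyi)
            for (int dxi = 0; dxi < 2; ++dxi) {
              const double wgt = (dxi ? wx[ox] : 1 - wx[ox]) *
                                 (dyi ? wy[oy] : 1 - wy[oy]) *
                                 (dz ? wz[oz] : 1 - wz[oz]);
              if (wgt == 0) continue;
              const int ix = dxi ? x1[ox] : x0[ox];
              const int iy = dyi ? y1[oy] : y0[oy];
              const int iz = dz ? z1[oz] : z0[oz];
              double* dst = dxp + (size_t)C * (ix + (size_t)X * (iy + (size_t)Y * iz));
              for (int c = 0; c < C; ++c) dst[c] += wgt * g[c];
            }
      }
  return dx;
}

// ---------------------------------------------------------------------------
// Slice-wise Canny edge detection along the third (axial) axis.
// Thresholds are fractions of each slice's maximum gradient magnitude.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector cpp_canny_slices(NumericVector vol, IntegerVector dims,
                               double sigma, double low_frac, double high_frac) {
  const int X = dims[0], Y = dims[1], Z = dims[2];
  IntegerVector out((R_xlen_t)X * Y * Z);
  const double* vp = REAL(vol);
  int* op = INTEGER(out);

  // Gaussian kernel
  const int r = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> gk(2 * r + 1);
  double gs = 0;
  for (int i = -r; i <= r; ++i) {
    gk[i + r] = std::exp(-0.5 * i * i / (sigma * sigma));
    gs += gk[i + r];
  }
  for (double& v : gk) v /= gs;

  std::vector<double> sl(X * Y), tmp(X * Y), sm(X * Y), gx(X * Y), gy(X * Y),
      mag(X * Y), nms(X * Y);
  std::vector<int> strong;

  for (int z = 0; z < Z; ++z) {
    for (int j = 0; j < Y; ++j)
      for (int i = 0; i < X; ++i)
        sl[i + X * j] = vp[i + (size_t)X * (j + (size_t)Y * z)];
    // separable Gaussian, clamped borders
    for (int j = 0; j < Y; ++j)
      for (int i = 0; i < X; ++i) {
        double s = 0;
        for (int t = -r; t <= r; ++t) s += gk[t + r] * sl[clampi(i + t, 0, X - 1) + X * j];
        tmp[i + X * j] = s;
      }
    for (int j = 0; j < Y; ++j)
      for (int i = 0; i < X; ++i) {
        double s = 0;
        for (int t = -r; t <= r; ++t) s += gk[t + r] * tmp[i + X * clampi(j + t, 0, Y - 1)];
        sm[i + X * j] = s;
      }
    // Sobel gradients, clamped borders
    double mmax = 0;
    for (int j = 0; j < Y; ++j)
      for (int i = 0; i < X; ++i) {
        const int im = clampi(i - 1, 0, X - 1), ip = clampi(i + 1, 0, X - 1);
        const int jm = clampi(j - 1, 0, Y - 1), jp = clampi(j + 1, 0, Y - 1);
        const double dgx = (sm[ip + X * jm] + 2 * sm[ip + X * j] + sm[ip + X * jp]) -
                           (sm[im + X * jm] + 2 * sm[im + X * j] + sm[im + X * jp]);
        const double dgy = (sm[im + X * jp] + 2 * sm[i + X * jp] + sm[ip + X * jp]) -
                           (sm[im + X * jm] + 2 * sm[i + X * jm] + sm[ip + X * jm]);
        gx[i + X * j] = dgx;
        gy[i + X * j] = dgy;
        const double m = std::sqrt(dgx * dgx + dgy * dgy);
        mag[i + X * j] = m;
        if (m > mmax) mmax = m;
      }
    if (mmax <= 0) continue;
    // non-maximum suppression, 4 quantised directions
    for (int j = 0; j < Y; ++j)
      for (int i = 0; i < X; ++i) {
        const double m = mag[i + X * j];
        nms[i + X * j] = 0;
        if (m == 0) continue;
        double deg = std::atan2(gy[i + X * j], gx[i + X * j]) * 180.0 / M_PI;
        deg += 180.0;                       // into [0, 360)
        while (deg >= 180.0) deg -= 180.0;  // orientation mod 180
        int di, dj;
        if (deg < 22.5 || deg >= 157.5) { di = 1; dj = 0; }
        else if (deg < 67.5) { di = 1; dj = 1; }
        else if (deg < 112.5) { di = 0; dj = 1; }
        else { di = -1; dj = 1; }
        const auto nb = [&](int a, int b) -> double {
          if (a < 0 || a >= X || b < 0 || b >= Y) return 0.0;
          return mag[a + X * b];
        };
        if (m >= nb(i + di, j + dj) && m >= nb(i - di, j - dj)) nms[i + X * j] = m;
      }
    const double high = high_frac * mmax, low = low_frac * mmax;
    strong.clear();
    std::vector<char> state(X * Y, 0);  // 0 none, 1 weak, 2 edge
    for (int q = 0; q < X * Y; ++q) {
      if (nms[q] >= high) { state[q] = 2; strong.push_back(q); }
      else if (nms[q] >= low) state[q] = 1;
    }
    // hysteresis: grow edges into 8-connected weak pixels
    while (!strong.empty()) {
      const int q = strong.back();
      strong.pop_back();
      const int i = q % X, j = q / X;
      for (int dj = -1; dj <= 1; ++dj)
        for (int di = -1; di <= 1; ++di) {
          const int a = i + di, b = j + dj;
          if (a < 0 || a >= X || b < 0 || b >= Y) continue;
          const int p = a + X * b;
          if (state[p] == 1) { state[p] = 2; strong.push_back(p); }
        }
    }
    for (int j = 0; j < Y; ++j)
      for (int i = 0; i < X; ++i)
        if (state[i + X * j] == 2) op[i + (size_t)X * (j + (size_t)Y * z)] = 1;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Exact squared Euclidean distance transform (lower-envelope algorithm),
// anisotropic voxel spacing in mm. Returns squared distance to the nearest
// foreground voxel; a large sentinel where the mask is empty.
// ---------------------------------------------------------------------------

static const double EDT_INF = 1e15;

static void dt1d(const double* f, double* d, int n, double w) {
  std::vector<int> v(n);
  std::vector<double> zb(n + 1);
  int k = 0;
  v[0] = 0;
  zb[0] = -EDT_INF;
  zb[1] = EDT_INF;
  for (int q = 1; q < n; ++q) {
    const double xq = q * w;
    double s;
    while (true) {
      const double xv = v[k] * w;
      s = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2 * xq - 2 * xv);
      if (s <= zb[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    zb[k] = s;
    zb[k + 1] = EDT_INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    const double xq = q * w;
    while (zb[k + 1] < xq) ++k;
    const double xv = v[k] * w;
    d[q] = (xq - xv) * (xq - xv) + f[v[k]];
    if (d[q] > EDT_INF) d[q] = EDT_INF;
  }
}

// [[Rcpp::export]]
NumericVector cpp_edt_sq(IntegerVector mask, IntegerVector dims,
                         NumericVector spacing) {
  const int X = dims[0], Y = dims[1], Z = dims[2];
  NumericVector out((R_xlen_t)X * Y * Z);
  double* dp = REAL(out);
  const int* mp = INTEGER(mask);
  for (R_xlen_t q = 0; q < out.size(); ++q) dp[q] = mp[q] ? 0.0 : EDT_INF;
  std::vector<double> f(std::max(X, std::max(Y, Z))), d(f.size());
  // along x
  for (int z = 0; z < Z; ++z)
    for (int y = 0; y < Y; ++y) {
      double* row = dp + (size_t)X * (y + (size_t)Y * z);
      dt1d(row, d.data(), X, spacing[0]);
      std::copy(d.begin(), d.begin() + X, row);
    }
  // along y
  for (int z = 0; z < Z; ++z)
    for (int x = 0; x < X; ++x) {
      for (int y = 0; y < Y; ++y) f[y] = dp[x + (size_t)X * (y + (size_t)Y * z)];
      dt1d(f.data(), d.data(), Y, spacing[1]);
      for (int y = 0; y < Y; ++y) dp[x + (size_t)X * (y + (size_t)Y * z)] = d[y];
    }
  // along z
  for (int y = 0; y < Y; ++y)
    for (int x = 0; x < X; ++x) {
      for (int z = 0; z < Z; ++z) f[z] = dp[x + (size_t)X * (y + (size_t)Y * z)];
      dt1d(f.data(), d.data(), Z, spacing[2]);
      for (int z = 0; z < Z; ++z) dp[x + (size_t)X * (y + (size_t)Y * z)] = d[z];
    }
  return out;
}

// ---------------------------------------------------------------------------
// Binary morphology with a ball structuring element (radius in voxels).
// Outside the volume counts as background.
// ---------------------------------------------------------------------------

static std::vector<std::array<int, 3>> ball_offsets(int r) {
  std::vector<std::array<int, 3>> off;
  for (int z = -r; z <= r; ++z)
    for (int y = -r; y <= r; ++y)
      for (int x = -r; x <= r; ++x)
        if (x * x + y * y + z * z <= r * r) off.push_back({x, y, z});
  return off;
}

// [[Rcpp::export]]
IntegerVector cpp_ball_morph(IntegerVector mask, IntegerVector dims, int radius,
                             bool dilate) {
  const int X = dims[0], Y = dims[1], Z = dims[2];
  const auto off = ball_offsets(radius);
  IntegerVector out((R_xlen_t)X * Y * Z);
  const int* mp = INTEGER(mask);
  int* op = INTEGER(out);
  for (int z = 0; z < Z; ++z)
    for (int y = 0; y < Y; ++y)
      for (int x = 0; x < X; ++x) {
        bool hit = dilate ? false : true;
        for (const auto& o : off) {
          const int a = x + o[0], b = y + o[1], c = z + o[2];
          int v = 0;
          if (a >= 0 && a < X && b >= 0 && b < Y && c >= 0 && c < Z)
            v = mp[a + (size_t)X * (b + (size_t)Y * c)];
          if (dilate) {
            if (v) { hit = true; break; }
          } else {
            if (!v) { hit = false; break; }
          }
        }
        op[x + (size_t)X * (y + (size_t)Y * z)] = hit ? 1 : 0;
      }
  return out;
}
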