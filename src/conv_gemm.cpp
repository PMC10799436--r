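// BLAS-backed 3D convolution: im2col patch extraction + dgemm. Layouts as in
// ops.cpp: x (nx,ny,nz,ci,b), w (k,k,k,ci,co), 'same' padding (k-1)/2.
#define USE_FC_LEN_T
#include <Rcpp.h>
#include <R_ext/BLAS.h>
#include <vector>
#ifndef FCONE
# define FCONE
#endif
using namespace Rcpp;

// Fill column-major P (nvox x k^3*nci): row = output voxel (x fastest),
// column = kernel tap (kx,ky,kz,ci). Zero padding outside the input.
static void im2col(const double *X, int nx, int ny, int nz, int nci,
                   int k, int s, int mx, int my, int mz, double *P) {
  const int pad = (k - 1) / 2;
  const R_xlen_t nvox = (R_xlen_t)mx * my * mz;
  R_xlen_t col = 0;
  for (int ci = 0; ci < nci; ci++) {
    const double *Xc = X + (R_xlen_t)ci * nx * ny * nz;
    for (int kz = 0; kz < k; kz++)
    for (int ky = 0; ky < k; ky++)
    for (int kx = 0; kx < k; kx++, col++) {
      double *Pc = P + col * nvox;
      const int dxo = kx - pad, dyo = ky - pad, dzo = kz - pad;
      R_xlen_t o = 0;
      for (int oz = 0; oz < mz; oz++) {
        const int iz = oz * s + dzo;
        if (iz < 0 || iz >= nz) {
          for (R_xlen_t i = 0; i < (R_xlen_t)my * mx; i++) Pc[o++] = 0.0;
          continue;
        }
        for (int oy = 0; oy < my; oy++) {
          const int iy = oy * s + dyo;
          if (iy < 0 || iy >= ny) {
            for (int i = 0; i < mx; i++) Pc[o++] = 0.0;
            continue;
          }
          const double *xrow = Xc + (R_xlen_t)nx * (iy + (R_xlen_t)ny * iz);
          if (s == 1) {
            int ox = 0;
            for (; ox < mx && ox + dxo < 0; ox++) Pc[o++] = 0.0;
            for (; ox < mx && ox + dxo < nx; ox++) Pc[o++] = xrow[ox + dxo];
            for (; ox < mx; ox++) Pc[o++] = 0.0;
          } else {
            for (int ox = 0; ox < mx; ox++) {
              const int ix = ox * s + dxo;
              Pc[o++] = (ix < 0 || ix >= nx) ? 0.0 : xrow[ix];
            }
          }
        }
      }
    }
  }
}

// Scatter-add of a patch-gradient matrix back to input space (transpose of
// im2col).
static void col2im(const double *P, int nx, int ny, int nz, int nci,
                   int k, int s, int mx, int my, int mz, double *GX) {
  const int pad = (k - 1) / 2;
  const R_xlen_t nvox = (R_xlen_t)mx * my * mz;
  R_xlen_t col = 0;
  for (int ci = 0; ci < nci; ci++) {
    double *Gc = GX + (R_xlen_t)ci * nx * ny * nz;
    for (int kz = 0; kz < k; kz++)
    for (int ky = 0; ky < k; ky++)
    for (int kx = 0; kx < k; kx++, col++) {
      const double *Pc = P + col * nvox;
      const int dxo = kx - pad, dyo = ky - pad, dzo = kz - pad;
      for (int oz = 0; oz < mz; oz++) {
        const int iz = oz * s + dzo;
        if (iz < 0 || iz >= nz) continue;
        for (int oy = 0; oy < my; oy++) {
          const int iy = oy * s + dyo;
          if (iy < 0 || iy >= ny) continue;
          double *grow = Gc + (R_xlen_t)nx * (iy + (R_xlen_t)ny * iz);
          const double *prow = Pc + (R_xlen_t)mx * (oy + (R_xlen_t)my * oz);
          if (s == 1) {
            const int ox0 = dxo < 0 ? -dxo : 0;
            const int ox1 = nx - dxo < mx ? nx - dxo : mx;
            for (int ox = ox0; ox < ox1; ox++) grow[ox + dxo] += prow[ox];
          } else {
            for (int ox = 0; ox < mx; ox++) {
              const int ix = ox * s + dxo;
              if (ix >= 0 && ix < nx) grow[ix] += prow[ox];
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv3d_fwd_gemm(NumericVector x, NumericVector w,
                                  NumericVector bias, int stride) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int nx = xd[0], ny = xd[1], nz = xd[2], nci = xd[3], nb = xd[4];
  const int k = wd[0], nco = wd[4];
  const int s = stride;
  const int mx = (nx + s - 1) / s, my = (ny + s - 1) / s, mz = (nz + s - 1) / s;
  const R_xlen_t nvox = (R_xlen_t)mx * my * mz;
  const int K = k * k * k * nci;

  NumericVector y(nvox * nco * nb);
  y.attr("dim") = IntegerVector::create(mx, my, mz, nco, nb);
  std::vector<double> P((size_t)nvox * K);
  const double one = 1.0, zero = 0.0;
  const int m_ = (int)nvox, n_ = nco, k_ = K;
  for (int b = 0; b < nb; b++) {
    im2col(x.begin() + (R_xlen_t)b * nx * ny * nz * nci,
           nx, ny, nz, nci, k, s, mx, my, mz, P.data());
    double *Yb = y.begin() + (R_xlen_t)b * nvox * nco;
    F77_CALL(dgemm)("N", "N", &m_, &n_, &k_, &one, P.data(), &m_,
                    w.begin(), &k_, &zero, Yb, &m_ FCONE FCONE);
    for (int co = 0; co < nco; co++) {
      const double bv = bias[co];
      double *Yc = Yb + (R_xlen_t)co * nvox;
      for (R_xlen_t i = 0; i < nvox; i++) Yc[i] += bv;
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv3d_bwd_gemm(NumericVector x, NumericVector w, NumericVector gy,
                         int stride) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int nx = xd[0], ny = xd[1], nz = xd[2], nci = xd[3], nb = xd[4];
  const int k = wd[0], nco = wd[4];
  const int s = stride;
  const int mx = (nx + s - 1) / s, my = (ny + s - 1) / s, mz = (nz + s - 1) / s;
  const R_xlen_t nvox = (R_xlen_t)mx * my * mz;
  const int K = k * k * k * nci;

  NumericVector gx(x.size());
  gx.attr("dim") = xd;
  NumericVector gw(w.size());
  gw.attr("dim") = wd;
  NumericVector gb(nco);
  std::vector<double> P((size_t)nvox * K), GP((size_t)nvox * K);
  const double one = 1.0, zero = 0.0;
  const int m_ = (int)nvox, n_ = nco, k_ = K;
  for (int b = 0; b < nb; b++) {
    const double *Xb = x.begin() + (R_xlen_t)b * nx * ny * nz * nci;
    const double *Gb = gy.begin() + (R_xlen_t)b * nvox * nco;
    im2col(Xb, nx, ny, nz, nci, k, s, mx, my, mz, P.data());
    // gw += P^T %*% gy_b : (K x nvox)(nvox x nco)
    F77_CALL(dgemm)("T", "N", &k_, &n_, &m_, &one, P.data(), &m_,
                    Gb, &m_, &one, gw.begin(), &k_ FCONE FCONE);
    // gP = gy_b %*% W^T : (nvox x nco)(nco x K)
    F77_CALL(dgemm)("N", "T", &m_, &k_, &n_, &one, Gb, &m_,
                    w.begin(), &k_, &zero, GP.data(), &m_ FCONE FCONE);
    col2im(GP.data(), nx, ny, nz, nci, k, s, mx, my, mz,
           gx.begin() + (R_xlen_t)b * nx * ny * nz * nci);
    for (int co = 0; co < nco; co++) {
      const double *Gc = Gb + (R_xlen_t)co * nvox;
      double acc = 0.0;
      for (R_xlen_t i = 0; i < nvox; i++) acc += Gc[i];
      gb[co] += acc;
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}
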