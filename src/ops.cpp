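#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Volumetric tensors are column-major R arrays laid out (x, y, z, channel, batch);
// kernels are (kx, ky, kz, in_channel, out_channel). All convolutions use 'same'
// padding of (k-1)/2, so odd kernel edges are assumed (checked in R).

static inline int ceil_div_nonneg(int a, int s) {
  if (a <= 0) return 0;
  return (a + s - 1) / s;
}

// [[Rcpp::export]]
NumericVector cpp_conv3d_fwd(NumericVector x, NumericVector w, NumericVector bias,
                             int stride) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int nx = xd[0], ny = xd[1], nz = xd[2], nci = xd[3], nb = xd[4];
  const int k = wd[0], nco = wd[4];
  const int pad = (k - 1) / 2, s = stride;
  const int mx = (nx + s - 1) / s, my = (ny + s - 1) / s, mz = (nz + s - 1) / s;

  NumericVector y((R_xlen_t)mx * my * mz * nco * nb);
  y.attr("dim") = IntegerVector::create(mx, my, mz, nco, nb);

  const double *X = x.begin(), *W = w.begin();
  double *Y = y.begin();
  const R_xlen_t xs_c = (R_xlen_t)nx * ny * nz, xs_b = xs_c * nci;
  const R_xlen_t ys_c = (R_xlen_t)mx * my * mz, ys_b = ys_c * nco;

  for (int b = 0; b < nb; b++) {
    for (int co = 0; co < nco; co++) {
      double *Yc = Y + b * ys_b + co * ys_c;
      const double bv = bias[co];
      for (R_xlen_t i = 0; i < ys_c; i++) Yc[i] = bv;
      for (int ci = 0; ci < nci; ci++) {
        const double *Xc = X + b * xs_b + ci * xs_c;
        for (int kz = 0; kz < k; kz++)
        for (int ky = 0; ky < k; ky++)
        for (int kx = 0; kx < k; kx++) {
          const double wv = W[kx + (R_xlen_t)k * (ky + (R_xlen_t)k * (kz + (R_xlen_t)k * (ci + (R_xlen_t)nci * co)))];
          if (wv == 0.0) continue;
          const int dxo = kx - pad, dyo = ky - pad, dzo = kz - pad;
          if (nx - 1 - dxo < 0 || ny - 1 - dyo < 0 || nz - 1 - dzo < 0) continue;
          const int ox0 = ceil_div_nonneg(-dxo, s), ox1 = std::min(mx - 1, (nx - 1 - dxo) / s);
          const int oy0 = ceil_div_nonneg(-dyo, s), oy1 = std::min(my - 1, (ny - 1 - dyo) / s);
          const int oz0 = ceil_div_nonneg(-dzo, s), oz1 = std::min(mz - 1, (nz - 1 - dzo) / s);
          for (int oz = oz0; oz <= oz1; oz++) {
            const int iz = oz * s + dzo;
            for (int oy = oy0; oy <= oy1; oy++) {
              const int iy = oy * s + dyo;
              double *yp = Yc + (R_xlen_t)mx * (oy + (R_xlen_t)my * oz);
              const double *xp = Xc + (R_xlen_t)nx * (iy + (R_xlen_t)ny * iz) + dxo;
              if (s == 1) {
                for (int ox = ox0; ox <= ox1; ox++) yp[ox] += wv * xp[ox];
              } else {
                for (int ox = ox0; ox <= ox1; ox++) yp[ox] += wv * xp[(R_xlen_t)ox * s];
              }
            }
          }
        }
      }
    }
  }
  return y;
}

// Returns gradients w.r.t. input, kernel and bias given upstream gradient gy.
// [[Rcpp::export]]
List cpp_conv3d_bwd(NumericVector x, NumericVector w, NumericVector gy, int stride) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int nx = xd[0], ny = xd[1], nz = xd[2], nci = xd[3], nb = xd[4];
  const int k = wd[0], nco = wd[4];
  const int pad = (k - 1) / 2, s = stride;
  const int mx = (nx + s - 1) / s, my = (ny + s - 1) / s, mz = (nz + s - 1) / s;

  NumericVector gx(x.size());
  gx.attr("dim") = xd;
  NumericVector gw(w.size());
  gw.attr("dim") = wd;
  NumericVector gb(nco);

  const double *X = x.begin(), *W = w.begin(), *GY = gy.begin();
  double *GX = gx.begin(), *GW = gw.begin(), *GB = gb.begin();
  const R_xlen_t xs_c = (R_xlen_t)nx * ny * nz, xs_b = xs_c * nci;
  const R_xlen_t ys_c = (R_xlen_t)mx * my * mz, ys_b = ys_c * nco;

  for (int b = 0; b < nb; b++) {
    for (int co = 0; co < nco; co++) {
      const double *Gc = GY + b * ys_b + co * ys_c;
      double acc_b = 0.0;
      for (R_xlen_t i = 0; i < ys_c; i++) acc_b += Gc[i];
      GB[co] += acc_b;
      for (int ci = 0; ci < nci; ci++) {
        const double *Xc = X + b * xs_b + ci * xs_c;
        double *GXc = GX + b * xs_b + ci * xs_c;
        for (int kz = 0; kz < k; kz++)
        for (int ky = 0; ky < k; ky++)
        for (int kx = 0; kx < k; kx++) {
          const R_xlen_t widx = kx + (R_xlen_t)k * (ky + (R_xlen_t)k * (kz + (R_xlen_t)k * (ci + (R_xlen_t)nci * co)));
          const double wv = W[widx];
          const int dxo = kx - pad, dyo = ky - pad, dzo = kz - pad;
          if (nx - 1 - dxo < 0 || ny - 1 - dyo < 0 || nz - 1 - dzo < 0) continue;
          const int ox0 = ceil_div_nonneg(-dxo, s), ox1 = std::min(mx - 1, (nx - 1 - dxo) / s);
          const int oy0 = ceil_div_nonneg(-dyo, s), oy1 = std::min(my - 1, (ny - 1 - dyo) / s);
          const int oz0 = ceil_div_nonneg(-dzo, s), oz1 = std::min(mz - 1, (nz - 1 - dzo) / s);
          double acc_w = 0.0;
          for (int oz = oz0; oz <= oz1; oz++) {
            const int iz = oz * s + dzo;
            for (int oy = oy0; oy <= oy1; oy++) {
              const int iy = oy * s + dyo;
              const double *gp = Gc + (R_xlen_t)mx * (oy + (R_xlen_t)my * oz);
              const double *xp = Xc + (R_xlen_t)nx * (iy + (R_xlen_t)ny * iz) + dxo;
              double *gxp = GXc + (R_xlen_t)nx * (iy + (R_xlen_t)ny * iz) + dxo;
              if (s == 1) {
                for (int ox = ox0; ox <= ox1; ox++) {
                  acc_w += gp[ox] * xp[ox];
                  gxp[ox] += wv * gp[ox];
                }
              } else {
                for (int ox = ox0; ox <= ox1; ox++) {
                  acc_w += gp[ox] * xp[(R_xlen_t)ox * s];
                  gxp[(R_xlen_t)ox * s] += wv * gp[ox];
                }
              }
            }
          }
          GW[widx] += acc_w;
        }
      }
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// Max pooling with window == stride; spatial dims must be divisible by win.
// Returns the pooled tensor and 1-based flat indices of each maximum into x.
// [[Rcpp::export]]
List cpp_maxpool_fwd(NumericVector x, int win) {
  IntegerVector xd = x.attr("dim");
  const int nx = xd[0], ny = xd[1], nz = xd[2], nc = xd[3], nb = xd[4];
  const int mx = nx / win, my = ny / win, mz = nz / win;
  NumericVector y((R_xlen_t)mx * my * mz * nc * nb);
  y.attr("dim") = IntegerVector::create(mx, my, mz, nc, nb);
  NumericVector arg(y.size());  // double to hold large flat indices safely
  const double *X = x.begin();
  double *Y = y.begin(), *A = arg.begin();
  R_xlen_t o = 0;
  for (int b = 0; b < nb; b++)
  for (int c = 0; c < nc; c++) {
    const R_xlen_t base = ((R_xlen_t)b * nc + c) * nx * ny * nz;
    for (int oz = 0; oz < mz; oz++)
    for (int oy = 0; oy < my; oy++)
    for (int ox = 0; ox < mx; ox++) {
      double best = R_NegInf;
      R_xlen_t besti = -1;
      for (int dz = 0; dz < win; dz++)
      for (int dy = 0; dy < win; dy++)
      for (int dx = 0; dx < win; dx++) {
        const int ix = ox * win + dx, iy = oy * win + dy, iz = oz * win + dz;
        const R_xlen_t idx = base + ix + (R_xlen_t)nx * (iy + (R_xlen_t)ny * iz);
        if (X[idx] > best) { best = X[idx]; besti = idx; }
      }
      Y[o] = best;
      A[o] = (double)(besti + 1);
      o++;
    }
  }
  return List::create(_["y"] = y, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bwd(NumericVector gy, NumericVector argmax, IntegerVector xdim) {
  R_xlen_t n = 1;
  for (int i = 0; i < xdim.size(); i++) n *= xdim[i];
  NumericVector gx(n);
  gx.attr("dim") = xdim;
  double *GX = gx.begin();
  const double *G = gy.begin(), *A = argmax.begin();
  for (R_xlen_t i = 0; i < gy.size(); i++) GX[(R_xlen_t)A[i] - 1] += G[i];
  return gx;
}

// Nearest-neighbour upsampling by integer factor f on the three spatial dims.
// [[Rcpp::export]]
NumericVector cpp_upsample_nn_fwd(NumericVector x, int f) {
  IntegerVector xd = x.attr("dim");
  const int nx = xd[0], ny = xd[1], nz = xd[2], nc = xd[3], nb = xd[4];
  const int mx = nx * f, my = ny * f, mz = nz * f;
  NumericVector y((R_xlen_t)mx * my * mz * nc * nb);
  y.attr("dim") = IntegerVector::create(mx, my, mz, nc, nb);
  const double *X = x.begin();
  double *Y = y.begin();
  R_xlen_t o = 0;
  for (int b = 0; b < nb; b++)
  for (int c = 0; c < nc; c++) {
    const R_xlen_t base = ((R_xlen_t)b * nc + c) * nx * ny * nz;
    for (int oz = 0; oz < mz; oz++)
    for (int oy = 0; oy < my; oy++) {
      const R_xlen_t row = base + (R_xlen_t)nx * ((oy / f) + (R_xlen_t)ny * (oz / f));
      for (int ox = 0; ox < mx; ox++) Y[o++] = X[row + ox / f];
    }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_upsample_nn_bwd(NumericVector gy, int f) {
  IntegerVector yd = gy.attr("dim");
  const int mx = yd[0], my = yd[1], mz = yd[2], nc = yd[3], nb = yd[4];
  const int nx = mx / f, ny = my / f, nz = mz / f;
  NumericVector gx((R_xlen_t)nx * ny * nz * nc * nb);
  gx.attr("dim") = IntegerVector::create(nx, ny, nz, nc, nb);
  const double *G = gy.begin();
  double *GX = gx.begin();
  R_xlen_t o = 0;
  for (int b = 0; b < nb; b++)
  for (int c = 0; c < nc; c++) {
    const R_xlen_t base = ((R_xlen_t)b * nc + c) * nx * ny * nz;
    for (int oz = 0; oz < mz; oz++)
    for (int oy = 0; oy < my; oy++) {
      const R_xlen_t row = base + (R_xlen_t)nx * ((oy / f) + (R_xlen_t)ny * (oz / f));
      for (int ox = 0; ox < mx; ox++) GX[row + ox / f] += G[o++];
    }
  }
  return gx;
}

// Connected-component labelling of a 3D logical mask (6 or 26 connectivity).
// Returns an integer array of component labels (0 = background).
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dims, int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n);
  lab.attr("dim") = dims;
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t seed = 0; seed < n; seed++) {
    if (!mask[seed] || lab[seed] != 0) continue;
    next++;
    lab[seed] = next;
    stack.clear();
    stack.push_back(seed);
    while (!stack.empty()) {
      const R_xlen_t cur = stack.back();
      stack.pop_back();
      const int cx = cur % nx, cy = (cur / nx) % ny, cz = cur / ((R_xlen_t)nx * ny);
      for (int dz = -1; dz <= 1; dz++)
      for (int dy = -1; dy <= 1; dy++)
      for (int dx = -1; dx <= 1; dx++) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        if (connectivity == 6 && (std::abs(dx) + std::abs(dy) + std::abs(dz)) != 1) continue;
        const int ix = cx + dx, iy = cy + dy, iz = cz + dz;
        if (ix < 0 || iy < 0 || iz < 0 || ix >= nx || iy >= ny || iz >= nz) continue;
        const R_xlen_t idx = ix + (R_xlen_t)nx * (iy + (R_xlen_t)ny * iz);
        if (mask[idx] && lab[idx] == 0) {
          lab[idx] = next;
          stack.push_back(idx);
        }
      }
    }
  }
  return lab;
}
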