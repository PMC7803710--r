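#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
#include <cstdio>
using namespace Rcpp;

// Linear index helpers: R arrays are column-major, 0-based here.
static inline R_xlen_t lin(int i, int j, int k, int nx, int ny) {
  return (R_xlen_t)i + (R_xlen_t)nx * ((R_xlen_t)j + (R_xlen_t)ny * k);
}

// Resample src onto a target grid through the affine index map
//   s = M %*% t + off   (continuous 0-based source index for target index t).
// interpolation: 0 = trilinear, 1 = nearest. Outside source -> fill (may be NA).
// [[Rcpp::export]]
NumericVector cpp_resample(NumericVector src, IntegerVector sdim,
                           IntegerVector tdim, NumericMatrix M,
                           NumericVector off, int nearest, double fill) {
  const int sx = sdim[0], sy = sdim[1], sz = sdim[2];
  const int tx = tdim[0], ty = tdim[1], tz = tdim[2];
  NumericVector out((R_xlen_t)tx * ty * tz);
  const double m00 = M(0,0), m01 = M(0,1), m02 = M(0,2);
  const double m10 = M(1,0), m11 = M(1,1), m12 = M(1,2);
  const double m20 = M(2,0), m21 = M(2,1), m22 = M(2,2);
  const double o0 = off[0], o1 = off[1], o2 = off[2];
  R_xlen_t p = 0;
  for (int k = 0; k < tz; ++k) {
    for (int j = 0; j < ty; ++j) {
      const double bx = m01 * j + m02 * k + o0;
      const double by = m11 * j + m12 * k + o1;
      const double bz = m21 * j + m22 * k + o2;
      for (int i = 0; i < tx; ++i, ++p) {
        const double u = m00 * i + bx;
        const double v = m10 * i + by;
        const double w = m20 * i + bz;
        if (nearest) {
          const int iu = (int)std::lround(u), iv = (int)std::lround(v),
                    iw = (int)std::lround(w);
          if (iu < 0 || iv < 0 || iw < 0 || iu >= sx || iv >= sy || iw >= sz)
            out[p] = fill;
          else
            out[p] = src[lin(iu, iv, iw, sx, sy)];
        } else {
          if (u < 0 || v < 0 || w < 0 || u > sx - 1 || v > sy - 1 || w > sz - 1) {
            out[p] = fill;
            continue;
          }
          int i0 = (int)std::floor(u), j0 = (int)std::floor(v),
              k0 = (int)std::floor(w);
          if (i0 == sx - 1) --i0;
          if (j0 == sy - 1) --j0;
          if (k0 == sz - 1) --k0;
          if (i0 < 0) i0 = 0;
          if (j0 < 0) j0 = 0;
          if (k0 < 0) k0 = 0;
          const double fx = u - i0, fy = v - j0, fz = w - k0;
          const double c000 = src[lin(i0,     j0,     k0,     sx, sy)];
          const double c100 = src[lin(i0 + 1, j0,     k0,     sx, sy)];
          const double c010 = src[lin(i0,     j0 + 1, k0,     sx, sy)];
          const double c110 = src[lin(i0 + 1, j0 + 1, k0,     sx, sy)];
          const double c001 = src[lin(i0,     j0,     k0 + 1, sx, sy)];
          const double c101 = src[lin(i0 + 1, j0,     k0 + 1, sx, sy)];
          const double c011 = src[lin(i0,     j0 + 1, k0 + 1, sx, sy)];
          const double c111 = src[lin(i0 + 1, j0 + 1, k0 + 1, sx, sy)];
          const double c00 = c000 + fx * (c100 - c000);
          const double c10 = c010 + fx * (c110 - c010);
          const double c01 = c001 + fx * (c101 - c001);
          const double c11 = c011 + fx * (c111 - c011);
          const double c0 = c00 + fy * (c10 - c00);
          const double c1 = c01 + fy * (c11 - c01);
          out[p] = c0 + fz * (c1 - c0);
        }
      }
    }
  }
  return out;
}

// Binary dilation/erosion with an explicit offset list (physical-space ball
// computed on the R side). Outside the array counts as background.
// [[Rcpp::export]]
LogicalVector cpp_morph(LogicalVector mask, IntegerVector dim,
                        IntegerMatrix offs, int dilate) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int no = offs.nrow();
  LogicalVector out((R_xlen_t)nx * ny * nz);
  std::vector<int> ox(no), oy(no), oz(no);
  for (int m = 0; m < no; ++m) {
    ox[m] = offs(m, 0); oy[m] = offs(m, 1); oz[m] = offs(m, 2);
  }
  R_xlen_t p = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i, ++p) {
        bool acc = !dilate;  // erode: AND over offsets, dilate: OR
        for (int m = 0; m < no; ++m) {
          const int ii = i + ox[m], jj = j + oy[m], kk = k + oz[m];
          bool val = false;
          if (ii >= 0 && jj >= 0 && kk >= 0 && ii < nx && jj < ny && kk < nz)
            val = mask[lin(ii, jj, kk, nx, ny)];
          if (dilate) { if (val) { acc = true; break; } }
          else        { if (!val) { acc = false; break; } }
        }
        out[p] = acc;
      }
  return out;
}

// Connected-component labelling (6 or 26 connectivity). Labels are assigned
// in raster-scan order, so label 1's seed has the lowest linear index.
// [[Rcpp::export]]
IntegerVector cpp_label(LogicalVector mask, IntegerVector dim, int connectivity) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n);  // zero-initialised
  std::vector<int> dxs, dys, dzs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        const int man = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && man != 1) continue;
        dxs.push_back(dx); dys.push_back(dy); dzs.push_back(dz);
      }
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    ++next;
    lab[s] = next;
    stack.push_back(s);
    while (!stack.empty()) {
      const R_xlen_t q = stack.back();
      stack.pop_back();
      const int i = (int)(q % nx), j = (int)((q / nx) % ny), k = (int)(q / ((R_xlen_t)nx * ny));
      for (size_t m = 0; m < dxs.size(); ++m) {
        const int ii = i + dxs[m], jj = j + dys[m], kk = k + dzs[m];
        if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
        const R_xlen_t r = lin(ii, jj, kk, nx, ny);
        if (mask[r] && !lab[r]) { lab[r] = next; stack.push_back(r); }
      }
    }
  }
  return lab;
}

// Fill cavities not connected to the volume border (6-connected background).
// [[Rcpp::export]]
LogicalVector cpp_fill_holes(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<char> outside(n, 0);
  std::vector<R_xlen_t> stack;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        if (i > 0 && i < nx - 1 && j > 0 && j < ny - 1 && k > 0 && k < nz - 1)
          continue;
        const R_xlen_t p = lin(i, j, k, nx, ny);
        if (!mask[p] && !outside[p]) { outside[p] = 1; stack.push_back(p); }
      }
  const int DX[6] = {1,-1,0,0,0,0}, DY[6] = {0,0,1,-1,0,0}, DZ[6] = {0,0,0,0,1,-1};
  while (!stack.empty()) {
    const R_xlen_t q = stack.back();
    stack.pop_back();
    const int i = (int)(q % nx), j = (int)((q / nx) % ny), k = (int)(q / ((R_xlen_t)nx * ny));
    for (int m = 0; m < 6; ++m) {
      const int ii = i + DX[m], jj = j + DY[m], kk = k + DZ[m];
      if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
      const R_xlen_t r = lin(ii, jj, kk, nx, ny);
      if (!mask[r] && !outside[r]) { outside[r] = 1; stack.push_back(r); }
    }
  }
  LogicalVector out(n);
  for (R_xlen_t p = 0; p < n; ++p) out[p] = mask[p] || !outside[p];
  return out;
}

// Separable Gaussian smoothing, per-axis sigma in voxel units, replicate edges.
static void gauss_axis(std::vector<double> &v, int nx, int ny, int nz,
                       int axis, double sigma) {
  if (sigma <= 0) return;
  const int rad = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> ker(2 * rad + 1);
  double s = 0;
  for (int m = -rad; m <= rad; ++m) {
    ker[m + rad] = std::exp(-0.5 * m * m / (sigma * sigma));
    s += ker[m + rad];
  }
  for (double &k : ker) k /= s;
  std::vector<double> line;
  const int len = axis == 0 ? nx : (axis == 1 ? ny : nz);
  line.resize(len);
  for (int a = 0; a < (axis == 0 ? ny : nx); ++a)
    for (int b = 0; b < (axis == 2 ? ny : nz); ++b) {
      for (int t = 0; t < len; ++t) {
        const int i = axis == 0 ? t : a;
        const int j = axis == 0 ? a : (axis == 1 ? t : b);
        const int k = axis == 2 ? t : b;
        line[t] = v[lin(i, j, k, nx, ny)];
      }
      for (int t = 0; t < len; ++t) {
        double acc = 0;
        for (int m = -rad; m <= rad; ++m) {
          int u = t + m;
          if (u < 0) u = 0;
          if (u >= len) u = len - 1;
          acc += ker[m + rad] * line[u];
        }
        const int i = axis == 0 ? t : a;
        const int j = axis == 0 ? a : (axis == 1 ? t : b);
        const int k = axis == 2 ? t : b;
        v[lin(i, j, k, nx, ny)] = acc;
      }
    }
}

// [[Rcpp::export]]
NumericVector cpp_gauss(NumericVector vol, IntegerVector dim,
                        NumericVector sigma_vox) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<double> v(vol.begin(), vol.end());
  gauss_axis(v, nx, ny, nz, 0, sigma_vox[0]);
  gauss_axis(v, nx, ny, nz, 1, sigma_vox[1]);
  gauss_axis(v, nx, ny, nz, 2, sigma_vox[2]);
  return NumericVector(v.begin(), v.end());
}

// Level-set mean-curvature flow: u_t = kappa * |grad u|, explicit Euler in
// voxel units. Edge-preserving: flat noise diffuses, coherent edges persist.
// [[Rcpp::export]]
NumericVector cpp_curvature_flow(NumericVector vol, IntegerVector dim,
                                 int iters, double dt) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<double> u(vol.begin(), vol.end()), un(n);
  const double eps = 1e-10;
  auto at = [&](const std::vector<double> &a, int i, int j, int k) {
    if (i < 0) i = 0; if (i >= nx) i = nx - 1;
    if (j < 0) j = 0; if (j >= ny) j = ny - 1;
    if (k < 0) k = 0; if (k >= nz) k = nz - 1;
    return a[lin(i, j, k, nx, ny)];
  };
  for (int it = 0; it < iters; ++it) {
    R_xlen_t p = 0;
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i, ++p) {
          const double uxp = at(u, i+1, j, k), uxm = at(u, i-1, j, k);
          const double uyp = at(u, i, j+1, k), uym = at(u, i, j-1, k);
          const double uzp = at(u, i, j, k+1), uzm = at(u, i, j, k-1);
          const double uc = u[p];
          const double ux = 0.5 * (uxp - uxm);
          const double uy = 0.5 * (uyp - uym);
          const double uz = 0.5 * (uzp - uzm);
          const double uxx = uxp - 2 * uc + uxm;
          const double uyy = uyp - 2 * uc + uym;
          const double uzz = uzp - 2 * uc + uzm;
          const double uxy = 0.25 * (at(u,i+1,j+1,k) - at(u,i+1,j-1,k)
                                   - at(u,i-1,j+1,k) + at(u,i-1,j-1,k));
          const double uxz = 0.25 * (at(u,i+1,j,k+1) - at(u,i+1,j,k-1)
                                   - at(u,i-1,j,k+1) + at(u,i-1,j,k-1));
          const double uyz = 0.25 * (at(u,i,j+1,k+1) - at(u,i,j+1,k-1)
                                   - at(u,i,j-1,k+1) + at(u,i,j-1,k-1));
          const double g2 = ux*ux + uy*uy + uz*uz;
          const double num = uxx * (uy*uy + uz*uz)
                           + uyy * (ux*ux + uz*uz)
                           + uzz * (ux*ux + uy*uy)
                           - 2 * (ux*uy*uxy + ux*uz*uxz + uy*uz*uyz);
          un[p] = uc + dt * num / (g2 + eps);
        }
    std::swap(u, un);
  }
  return NumericVector(u.begin(), u.end());
}

// Exact squared Euclidean distance transform (distance to nearest true voxel)
// with anisotropic spacing; Felzenszwalb-Huttenlocher lower envelope per axis.
static void edt_1d(std::vector<double> &f, std::vector<double> &d,
                   std::vector<int> &vtx, std::vector<double> &zz,
                   int n, double sp) {
  const double INF = 1e20;
  int kk = 0;
  vtx[0] = 0;
  zz[0] = -INF;
  zz[1] = INF;
  for (int q = 1; q < n; ++q) {
    const double xq = q * sp;
    double s;
    while (true) {
      const int p = vtx[kk];
      const double xp = p * sp;
      s = ((f[q] + xq * xq) - (f[p] + xp * xp)) / (2 * xq - 2 * xp);
      if (s <= zz[kk]) --kk; else break;
    }
    ++kk;
    vtx[kk] = q;
    zz[kk] = s;
    zz[kk + 1] = INF;
  }
  kk = 0;
  for (int q = 0; q < n; ++q) {
    const double xq = q * sp;
    while (zz[kk + 1] < xq) ++kk;
    const double xp = vtx[kk] * sp;
    d[q] = (xq - xp) * (xq - xp) + f[vtx[kk]];
  }
}

// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector mask, IntegerVector dim,
                         NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const double INF = 1e20;
  std::vector<double> D(n);
  for (R_xlen_t p = 0; p < n; ++p) D[p] = mask[p] ? 0.0 : INF;
  const int maxlen = std::max(nx, std::max(ny, nz));
  std::vector<double> f(maxlen), d(maxlen), zz(maxlen + 1);
  std::vector<int> vtx(maxlen);
  // x
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) f[i] = D[lin(i, j, k, nx, ny)];
      edt_1d(f, d, vtx, zz, nx, spacing[0]);
      for (int i = 0; i < nx; ++i) D[lin(i, j, k, nx, ny)] = d[i];
    }
  // y
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      for (int j = 0; j < ny; ++j) f[j] = D[lin(i, j, k, nx, ny)];
      edt_1d(f, d, vtx, zz, ny, spacing[1]);
      for (int j = 0; j < ny; ++j) D[lin(i, j, k, nx, ny)] = d[j];
    }
  // z
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      for (int k = 0; k < nz; ++k) f[k] = D[lin(i, j, k, nx, ny)];
      edt_1d(f, d, vtx, zz, nz, spacing[2]);
      for (int k = 0; k < nz; ++k) D[lin(i, j, k, nx, ny)] = d[k];
    }
  return NumericVector(D.begin(), D.end());
}

// Joint histogram of paired intensities with Parzen-style bilinear bin
// spreading, so histogram-based similarity metrics vary smoothly with the
// transform parameters. Pairs with NA in either value are skipped.
// [[Rcpp::export]]
NumericVector cpp_joint_hist(NumericVector a, NumericVector b, int bins,
                             double amin, double amax, double bmin, double bmax) {
  NumericVector h((R_xlen_t)bins * bins);
  const double ascale = bins / (amax - amin), bscale = bins / (bmax - bmin);
  const R_xlen_t n = a.size();
  for (R_xlen_t p = 0; p < n; ++p) {
    const double av = a[p], bv = b[p];
    if (ISNAN(av) || ISNAN(bv)) continue;
    double ca = (av - amin) * ascale - 0.5;
    double cb = (bv - bmin) * bscale - 0.5;
    if (ca < 0) ca = 0;
    if (cb < 0) cb = 0;
    if (ca > bins - 1) ca = bins - 1;
    if (cb > bins - 1) cb = bins - 1;
    const int ia = (int)ca, ib = (int)cb;
    const double fa = ca - ia, fb = cb - ib;
    const int ia1 = ia + 1 < bins ? ia + 1 : ia;
    const int ib1 = ib + 1 < bins ? ib + 1 : ib;
    h[ia  + (R_xlen_t)bins * ib ] += (1 - fa) * (1 - fb);
    h[ia1 + (R_xlen_t)bins * ib ] += fa * (1 - fb);
    h[ia  + (R_xlen_t)bins * ib1] += (1 - fa) * fb;
    h[ia1 + (R_xlen_t)bins * ib1] += fa * fb;
  }
  return h;
}

// FNV-1a 64-bit hash of a raw vector, as a hex string (content hashing for
// run manifests and deterministic DICOM UIDs).
// [[Rcpp::export]]
std::string cpp_fnv1a(RawVector bytes) {
  uint64_t h = 1469598103934665603ULL;
  const uint64_t prime = 1099511628211ULL;
  for (R_xlen_t i = 0; i < bytes.size(); ++i) {
    h ^= (uint64_t)bytes[i];
    h *= prime;
  }
  char buf[17];
  std::snprintf(buf, sizeof(buf), "%016llx", (unsigned long long)h);
  return std::string(buf);
}
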