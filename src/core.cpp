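#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Trilinear / nearest-neighbour sampling of a 3D volume at arbitrary
// continuous voxel coordinates (0-based). Out-of-bounds samples take `fill`.
// [[Rcpp::export]]
NumericVector cpp_sample_volume(NumericVector vol, IntegerVector dim,
                                NumericVector px, NumericVector py,
                                NumericVector pz, bool nearest, double fill) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = px.size();
  NumericVector out(n);
  const double *v = vol.begin();
  for (R_xlen_t t = 0; t < n; ++t) {
    double x = px[t], y = py[t], z = pz[t];
    if (nearest) {
      int ix = (int)std::lround(x), iy = (int)std::lround(y),
          iz = (int)std::lround(z);
      if (ix < 0 || iy < 0 || iz < 0 || ix >= nx || iy >= ny || iz >= nz) {
        out[t] = fill;
      } else {
        out[t] = v[(size_t)ix + nx * ((size_t)iy + (size_t)ny * iz)];
      }
    } else {
      if (x < 0 || y < 0 || z < 0 || x > nx - 1 || y > ny - 1 || z > nz - 1) {
        out[t] = fill;
        continue;
      }
      int ix = (int)std::floor(x), iy = (int)std::floor(y),
          iz = (int)std::floor(z);
      if (ix == nx - 1) ix--;
      if (iy == ny - 1) iy--;
      if (iz == nz - 1) iz--;
      double fx = x - ix, fy = y - iy, fz = z - iz;
      size_t i000 = (size_t)ix + nx * ((size_t)iy + (size_t)ny * iz);
      size_t sx = 1, sy = nx, sz = (size_t)nx * ny;
      double c00 = v[i000] * (1 - fx) + v[i000 + sx] * fx;
      double c10 = v[i000 + sy] * (1 - fx) + v[i000 + sy + sx] * fx;
      double c01 = v[i000 + sz] * (1 - fx) + v[i000 + sz + sx] * fx;
      double c11 = v[i000 + sz + sy] * (1 - fx) + v[i000 + sz + sy + sx] * fx;
      double c0 = c00 * (1 - fy) + c10 * fy;
      double c1 = c01 * (1 - fy) + c11 * fy;
      out[t] = c0 * (1 - fz) + c1 * fz;
    }
  }
  return out;
}

static inline void bspline_weights(double t, double *w) {
  double t2 = t * t, t3 = t2 * t;
  w[0] = (1 - 3 * t + 3 * t2 - t3) / 6.0;
  w[1] = (3 * t3 - 6 * t2 + 4) / 6.0;
  w[2] = (-3 * t3 + 3 * t2 + 3 * t + 1) / 6.0;
  w[3] = t3 / 6.0;
}

// Number of control points needed along an axis of `n` voxels with control
// spacing `s` voxels: lattice indices -1 .. floor((n-1)/s)+2 (0-based array).
// [[Rcpp::export]]
IntegerVector cpp_bspline_ncp(IntegerVector dim, double spacing) {
  IntegerVector out(3);
  for (int a = 0; a < 3; ++a)
    out[a] = (int)std::floor((dim[a] - 1) / spacing) + 4;
  return out;
}

// Dense displacement field from a cubic B-spline control-point lattice.
// cp is [ncx, ncy, ncz, 3]; returns [nx, ny, nz, 3] in the same units as cp.
// [[Rcpp::export]]
NumericVector cpp_bspline_field(NumericVector cp, IntegerVector ncp,
                                IntegerVector dim, double spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int cx = ncp[0], cy = ncp[1], cz = ncp[2];
  NumericVector out((R_xlen_t)nx * ny * nz * 3);
  const double *c = cp.begin();
  double *o = out.begin();
  const size_t cxy = (size_t)cx * cy, cvol = cxy * cz;
  const size_t nvol = (size_t)nx * ny * nz;
  std::vector<double> wx(4 * nx), wy(4 * ny), wz(4 * nz);
  std::vector<int> ix0(nx), iy0(ny), iz0(nz);
  for (int i = 0; i < nx; ++i) {
    double t = i / spacing; ix0[i] = (int)std::floor(t);
    bspline_weights(t - ix0[i], &wx[4 * i]);
  }
  for (int i = 0; i < ny; ++i) {
    double t = i / spacing; iy0[i] = (int)std::floor(t);
    bspline_weights(t - iy0[i], &wy[4 * i]);
  }
  for (int i = 0; i < nz; ++i) {
    double t = i / spacing; iz0[i] = (int)std::floor(t);
    bspline_weights(t - iz0[i], &wz[4 * i]);
  }
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        double acc[3] = {0, 0, 0};
        for (int l = 0; l < 4; ++l) {
          int ci = iz0[z] + l; double wl = wz[4 * z + l];
          for (int m = 0; m < 4; ++m) {
            int cj = iy0[y] + m; double wlm = wl * wy[4 * y + m];
            size_t base = cxy * ci + (size_t)cx * cj + ix0[x];
            for (int n = 0; n < 4; ++n) {
              double w = wlm * wx[4 * x + n];
              size_t idx = base + n;
              acc[0] += w * c[idx];
              acc[1] += w * c[idx + cvol];
              acc[2] += w * c[idx + 2 * cvol];
            }
          }
        }
        size_t vi = (size_t)x + nx * ((size_t)y + (size_t)ny * z);
        o[vi] = acc[0]; o[vi + nvol] = acc[1]; o[vi + 2 * nvol] = acc[2];
      }
  return out;
}

// Adjoint of cpp_bspline_field: accumulate a dense voxelwise force field
// [nx,ny,nz,3] onto the control-point lattice gradient [ncx,ncy,ncz,3].
// [[Rcpp::export]]
NumericVector cpp_bspline_splat(NumericVector force, IntegerVector ncp,
                                IntegerVector dim, double spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int cx = ncp[0], cy = ncp[1], cz = ncp[2];
  NumericVector out((R_xlen_t)cx * cy * cz * 3);
  const double *f = force.begin();
  double *o = out.begin();
  const size_t cxy = (size_t)cx * cy, cvol = cxy * cz;
  const size_t nvol = (size_t)nx * ny * nz;
  std::vector<double> wx(4 * nx), wy(4 * ny), wz(4 * nz);
  std::vector<int> ix0(nx), iy0(ny), iz0(nz);
  for (int i = 0; i < nx; ++i) {
    double t = i / spacing; ix0[i] = (int)std::floor(t);
    bspline_weights(t - ix0[i], &wx[4 * i]);
  }
  for (int i = 0; i < ny; ++i) {
    double t = i / spacing; iy0[i] = (int)std::floor(t);
    bspline_weights(t - iy0[i], &wy[4 * i]);
  }
  for (int i = 0; i < nz; ++i) {
    double t = i / spacing; iz0[i] = (int)std::floor(t);
    bspline_weights(t - iz0[i], &wz[4 * i]);
  }
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        size_t vi = (size_t)x + nx * ((size_t)y + (size_t)ny * z);
        double f0 = f[vi], f1 = f[vi + nvol], f2 = f[vi + 2 * nvol];
        if (f0 == 0 && f1 == 0 && f2 == 0) continue;
        for (int l = 0; l < 4; ++l) {
          int ci = iz0[z] + l; double wl = wz[4 * z + l];
          for (int m = 0; m < 4; ++m) {
            int cj = iy0[y] + m; double wlm = wl * wy[4 * y + m];
            size_t base = cxy * ci + (size_t)cx * cj + ix0[x];
            for (int n = 0; n < 4; ++n) {
              double w = wlm * wx[4 * x + n];
              size_t idx = base + n;
              o[idx] += w * f0;
              o[idx + cvol] += w * f1;
              o[idx + 2 * cvol] += w * f2;
            }
          }
        }
      }
  return out;
}

static void smooth_axis(std::vector<double> &buf, double *v, int nx, int ny,
                        int nz, int axis, double sigma) {
  if (sigma <= 0) return;
  int r = std::max(1, (int)std::ceil(3 * sigma));
  std::vector<double> k(2 * r + 1);
  for (int i = -r; i <= r; ++i) k[i + r] = std::exp(-0.5 * i * i / (sigma * sigma));
  const size_t sx = 1, sy = nx, sz = (size_t)nx * ny;
  size_t stride = axis == 0 ? sx : (axis == 1 ? sy : sz);
  int nax = axis == 0 ? nx : (axis == 1 ? ny : nz);
  int n1 = axis == 0 ? ny : nx;
  int n2 = axis == 2 ? ny : nz;
  size_t st1 = axis == 0 ? sy : sx;
  size_t st2 = axis == 2 ? sy : sz;
  buf.resize(nax);
  for (int b = 0; b < n2; ++b)
    for (int a = 0; a < n1; ++a) {
      double *line = v + st1 * a + st2 * b;
      for (int i = 0; i < nax; ++i) buf[i] = line[stride * i];
      for (int i = 0; i < nax; ++i) {
        double acc = 0, wsum = 0;
        int lo = std::max(0, i - r), hi = std::min(nax - 1, i + r);
        for (int j = lo; j <= hi; ++j) {
          double w = k[j - i + r];
          acc += w * buf[j]; wsum += w;
        }
        line[stride * i] = acc / wsum;
      }
    }
}

// Separable Gaussian smoothing with truncated, edge-renormalized kernels
// (preserves constants). sigma per axis, in voxels.
// [[Rcpp::export]]
NumericVector cpp_gauss_smooth(NumericVector vol, IntegerVector dim,
                               NumericVector sigma) {
  NumericVector out = clone(vol);
  std::vector<double> buf;
  for (int a = 0; a < 3; ++a)
    smooth_axis(buf, out.begin(), dim[0], dim[1], dim[2], a, sigma[a]);
  return out;
}

// Central-difference gradient; one-sided at faces. Returns [nx,ny,nz,3]
// in intensity units per voxel (divide by spacing for per-mm).
// [[Rcpp::export]]
NumericVector cpp_gradient3d(NumericVector vol, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const size_t nvol = (size_t)nx * ny * nz;
  NumericVector out(nvol * 3);
  const double *v = vol.begin();
  double *o = out.begin();
  const size_t sx = 1, sy = nx, sz = (size_t)nx * ny;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        size_t i = (size_t)x + nx * ((size_t)y + (size_t)ny * z);
        double gx = x == 0 ? v[i + sx] - v[i]
                  : (x == nx - 1 ? v[i] - v[i - sx]
                                 : 0.5 * (v[i + sx] - v[i - sx]));
        double gy = y == 0 ? v[i + sy] - v[i]
                  : (y == ny - 1 ? v[i] - v[i - sy]
                                 : 0.5 * (v[i + sy] - v[i - sy]));
        double gz = z == 0 ? v[i + sz] - v[i]
                  : (z == nz - 1 ? v[i] - v[i - sz]
                                 : 0.5 * (v[i + sz] - v[i - sz]));
        o[i] = gx; o[i + nvol] = gy; o[i + 2 * nvol] = gz;
      }
  return out;
}

// Sum of the 6-connected neighbour values for each of K stacked volumes
// [nx,ny,nz,K]; out-of-grid neighbours contribute 0.
// [[Rcpp::export]]
NumericVector cpp_neighbour_sum(NumericVector vols, IntegerVector dim, int k) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const size_t nvol = (size_t)nx * ny * nz;
  NumericVector out(nvol * k);
  const size_t sx = 1, sy = nx, sz = (size_t)nx * ny;
  for (int c = 0; c < k; ++c) {
    const double *v = vols.begin() + nvol * c;
    double *o = out.begin() + nvol * c;
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          size_t i = (size_t)x + nx * ((size_t)y + (size_t)ny * z);
          double acc = 0;
          if (x > 0) acc += v[i - sx];
          if (x < nx - 1) acc += v[i + sx];
          if (y > 0) acc += v[i - sy];
          if (y < ny - 1) acc += v[i + sy];
          if (z > 0) acc += v[i - sz];
          if (z < nz - 1) acc += v[i + sz];
          o[i] = acc;
        }
  }
  return out;
}
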