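#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static double sample3_cubic(const double *v, const int nx, const int ny,
                            const int nz, const double x, const double y,
                            const double z, const double fill);

// Trilinear sample of a 3D volume at 0-based voxel coordinates.
// Out-of-field -> fill.
static inline double sample3(const double *v, const int nx, const int ny,
                             const int nz, const double x, const double y,
                             const double z, const double fill) {
  if (x < 0.0 || y < 0.0 || z < 0.0 || x > nx - 1.0 || y > ny - 1.0 ||
      z > nz - 1.0)
    return fill;
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
  if (x0 > nx - 2) x0 = nx - 2;
  if (y0 > ny - 2) y0 = ny - 2;
  if (z0 > nz - 2) z0 = nz - 2;
  if (x0 < 0) x0 = 0;
  if (y0 < 0) y0 = 0;
  if (z0 < 0) z0 = 0;
  const double fx = x - x0, fy = y - y0, fz = z - z0;
  const int sx = 1, sy = nx, sz = nx * ny;
  const double *p = v + x0 * sx + y0 * sy + z0 * sz;
  const double c00 = p[0] * (1 - fx) + p[sx] * fx;
  const double c10 = p[sy] * (1 - fx) + p[sy + sx] * fx;
  const double c01 = p[sz] * (1 - fx) + p[sz + sx] * fx;
  const double c11 = p[sz + sy] * (1 - fx) + p[sz + sy + sx] * fx;
  const double c0 = c00 * (1 - fy) + c10 * fy;
  const double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

// Resample a 3D volume under an affine voxel->voxel map.
// M is 3x4; input voxel coord = M %*% c(out_i, out_j, out_k, 1), all 0-based.
// [[Rcpp::export]]
NumericVector resample_affine_cpp(NumericVector vol, IntegerVector dim,
                                  NumericMatrix M, double fill,
                                  bool cubic = false) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out(nx * ny * nz);
  const double *v = vol.begin();
  const double m00 = M(0, 0), m01 = M(0, 1), m02 = M(0, 2), m03 = M(0, 3);
  const double m10 = M(1, 0), m11 = M(1, 1), m12 = M(1, 2), m13 = M(1, 3);
  const double m20 = M(2, 0), m21 = M(2, 1), m22 = M(2, 2), m23 = M(2, 3);
  int idx = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i, ++idx) {
        const double x = m00 * i + m01 * j + m02 * k + m03;
        const double y = m10 * i + m11 * j + m12 * k + m13;
        const double z = m20 * i + m21 * j + m22 * k + m23;
        out[idx] = cubic ? sample3_cubic(v, nx, ny, nz, x, y, z, fill)
                         : sample3(v, nx, ny, nz, x, y, z, fill);
      }
  return out;
}

// Mean squared error between fixed and moving-resampled-under-M, over voxels
// where mask is true (mask may be empty => all voxels) whose sample falls
// in-field. Returns NA when fewer than half the eligible voxels remain
// in-field, so the optimizer cannot profit from shedding the overlap.
// [[Rcpp::export]]
double mse_affine_cpp(NumericVector moving, NumericVector fixed,
                      IntegerVector dim, NumericMatrix M,
                      LogicalVector mask, bool cubic = false) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const bool use_mask = mask.size() == nx * ny * nz;
  const double *mv = moving.begin();
  const double m00 = M(0, 0), m01 = M(0, 1), m02 = M(0, 2), m03 = M(0, 3);
  const double m10 = M(1, 0), m11 = M(1, 1), m12 = M(1, 2), m13 = M(1, 3);
  const double m20 = M(2, 0), m21 = M(2, 1), m22 = M(2, 2), m23 = M(2, 3);
  double ss = 0.0;
  long n = 0, n_total = 0;
  int idx = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i, ++idx) {
        if (use_mask && !mask[idx]) continue;
        ++n_total;
        const double x = m00 * i + m01 * j + m02 * k + m03;
        const double y = m10 * i + m11 * j + m12 * k + m13;
        const double z = m20 * i + m21 * j + m22 * k + m23;
        if (x < 0.0 || y < 0.0 || z < 0.0 || x > nx - 1.0 || y > ny - 1.0 ||
            z > nz - 1.0)
          continue;
        const double s = cubic ? sample3_cubic(mv, nx, ny, nz, x, y, z, 0.0)
                               : sample3(mv, nx, ny, nz, x, y, z, 0.0);
        const double d = s - fixed[idx];
        ss += d * d;
        ++n;
      }
  if (n == 0 || 2 * n < n_total) return NA_REAL;
  return ss / (double)n;
}

// Catmull-Rom cubic sampling (C1, exact for quadratics away from edges);
// used by the registration metric where trilinear smoothing bias matters.
static inline double cr_w(const double t, const int i) {
  switch (i) {
  case 0: return 0.5 * (-t + 2 * t * t - t * t * t);
  case 1: return 0.5 * (2 - 5 * t * t + 3 * t * t * t);
  case 2: return 0.5 * (t + 4 * t * t - 3 * t * t * t);
  default: return 0.5 * (-t * t + t * t * t);
  }
}

static inline int clampi(int i, const int n) {
  if (i < 0) return 0;
  if (i >= n) return n - 1;
  return i;
}

static double sample3_cubic(const double *v, const int nx,
                            const int ny, const int nz,
                            const double x, const double y,
                            const double z, const double fill) {
  if (x < 0.0 || y < 0.0 || z < 0.0 || x > nx - 1.0 || y > ny - 1.0 ||
      z > nz - 1.0)
    return fill;
  const int x0 = (int)std::floor(x), y0 = (int)std::floor(y),
            z0 = (int)std::floor(z);
  const double fx = x - x0, fy = y - y0, fz = z - z0;
  double wx[4], wy[4], wz[4];
  int ix[4], iy[4], iz[4];
  for (int a = 0; a < 4; ++a) {
    wx[a] = cr_w(fx, a); ix[a] = clampi(x0 - 1 + a, nx);
    wy[a] = cr_w(fy, a); iy[a] = clampi(y0 - 1 + a, ny);
    wz[a] = cr_w(fz, a); iz[a] = clampi(z0 - 1 + a, nz);
  }
  double acc = 0.0;
  for (int c = 0; c < 4; ++c) {
    const long off_z = (long)iz[c] * nx * ny;
    double accy = 0.0;
    for (int b = 0; b < 4; ++b) {
      const double *row = v + off_z + (long)iy[b] * nx;
      accy += wy[b] * (wx[0] * row[ix[0]] + wx[1] * row[ix[1]] +
                       wx[2] * row[ix[2]] + wx[3] * row[ix[3]]);
    }
    acc += wz[c] * accy;
  }
  return acc;
}

static inline int reflect_idx(int i, const int n) {
  // symmetric (half-sample) reflection; conserves mass under convolution
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

static void conv_axis(const double *in, double *out, const int nx, const int ny,
                      const int nz, const int nt, const int axis,
                      const NumericVector &kern) {
  const int r = (kern.size() - 1) / 2;
  const int dims[4] = {nx, ny, nz, nt};
  const int n = dims[axis];
  const long stride[4] = {1, (long)nx, (long)nx * ny, (long)nx * ny * nz};
  const long s = stride[axis];
  const long total = (long)nx * ny * nz * nt;
  // iterate over all lines along `axis`
  for (long base = 0; base < total; ++base) {
    // compute coordinate along axis for this linear index
    long rem = base;
    int coord[4];
    coord[0] = rem % nx; rem /= nx;
    coord[1] = rem % ny; rem /= ny;
    coord[2] = rem % nz; rem /= nz;
    coord[3] = (int)rem;
    const int c = coord[axis];
    double acc = 0.0;
    for (int q = -r; q <= r; ++q) {
      const int cc = reflect_idx(c + q, n);
      acc += kern[q + r] * in[base + (long)(cc - c) * s];
    }
    out[base] = acc;
  }
}

// Separable convolution of a 4D volume with per-axis 1D kernels
// (applied to the three spatial axes only), reflective boundaries.
// A kernel of length 1 (value 1) is an identity for that axis.
// [[Rcpp::export]]
NumericVector smooth4d_cpp(NumericVector vol, IntegerVector dim,
                           NumericVector kx, NumericVector ky,
                           NumericVector kz) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int nt = dim.size() > 3 ? dim[3] : 1;
  const long total = (long)nx * ny * nz * nt;
  NumericVector a(clone(vol));
  NumericVector b(total);
  double *pa = a.begin(), *pb = b.begin();
  const NumericVector *ks[3] = {&kx, &ky, &kz};
  bool in_a = true;
  for (int axis = 0; axis < 3; ++axis) {
    if (ks[axis]->size() <= 1) continue;
    if (in_a)
      conv_axis(pa, pb, nx, ny, nz, nt, axis, *ks[axis]);
    else
      conv_axis(pb, pa, nx, ny, nz, nt, axis, *ks[axis]);
    in_a = !in_a;
  }
  return in_a ? a : b;
}

// Binary dilation of a 3D mask with a 6-connected structuring element,
// repeated `iter` times.
// [[Rcpp::export]]
LogicalVector dilate3d_cpp(LogicalVector mask, IntegerVector dim, int iter) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  LogicalVector cur(clone(mask));
  LogicalVector nxt(nx * ny * nz);
  for (int it = 0; it < iter; ++it) {
    int idx = 0;
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i, ++idx) {
          bool v = cur[idx];
          if (!v) {
            if (i > 0 && cur[idx - 1]) v = true;
            else if (i < nx - 1 && cur[idx + 1]) v = true;
            else if (j > 0 && cur[idx - nx]) v = true;
            else if (j < ny - 1 && cur[idx + nx]) v = true;
            else if (k > 0 && cur[idx - nx * ny]) v = true;
            else if (k < nz - 1 && cur[idx + nx * ny]) v = true;
          }
          nxt[idx] = v;
        }
    std::copy(nxt.begin(), nxt.end(), cur.begin());
  }
  return cur;
}

// Binary erosion (6-connected), single pass repeated `iter` times.
// [[Rcpp::export]]
LogicalVector erode3d_cpp(LogicalVector mask, IntegerVector dim, int iter) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  LogicalVector cur(clone(mask));
  LogicalVector nxt(nx * ny * nz);
  for (int it = 0; it < iter; ++it) {
    int idx = 0;
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i, ++idx) {
          bool v = cur[idx];
          if (v) {
            if (i == 0 || !cur[idx - 1]) v = false;
            else if (i == nx - 1 || !cur[idx + 1]) v = false;
            else if (j == 0 || !cur[idx - nx]) v = false;
            else if (j == ny - 1 || !cur[idx + nx]) v = false;
            else if (k == 0 || !cur[idx - nx * ny]) v = false;
            else if (k == nz - 1 || !cur[idx + nx * ny]) v = false;
          }
          nxt[idx] = v;
        }
    std::copy(nxt.begin(), nxt.end(), cur.begin());
  }
  return cur;
}
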