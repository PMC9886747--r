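#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Trilinear / nearest sampling at 0-based continuous voxel coordinates.
// clamp = true replicates edge values (used inside registration);
// clamp = false returns `fill` outside the grid.
static inline double sample1(const double *v, int nx, int ny, int nz,
                             double x, double y, double z,
                             bool linear, bool clamp, double fill) {
  if (!clamp) {
    if (x < -0.5 || y < -0.5 || z < -0.5 ||
        x > nx - 0.5 || y > ny - 0.5 || z > nz - 0.5)
      return fill;
  }
  if (!linear) {
    int i = (int)std::lround(x), j = (int)std::lround(y), k = (int)std::lround(z);
    if (i < 0) { if (!clamp) return fill; i = 0; }
    if (j < 0) { if (!clamp) return fill; j = 0; }
    if (k < 0) { if (!clamp) return fill; k = 0; }
    if (i >= nx) { if (!clamp) return fill; i = nx - 1; }
    if (j >= ny) { if (!clamp) return fill; j = ny - 1; }
    if (k >= nz) { if (!clamp) return fill; k = nz - 1; }
    return v[i + (size_t)nx * (j + (size_t)ny * k)];
  }
  // linear: clamp coordinates to the valid interpolation domain
  double xc = x, yc = y, zc = z;
  if (xc < 0) xc = 0; if (xc > nx - 1) xc = nx - 1;
  if (yc < 0) yc = 0; if (yc > ny - 1) yc = ny - 1;
  if (zc < 0) zc = 0; if (zc > nz - 1) zc = nz - 1;
  if (!clamp && (x < 0 || y < 0 || z < 0 ||
                 x > nx - 1 || y > ny - 1 || z > nz - 1))
    return fill;
  int i0 = (int)std::floor(xc), j0 = (int)std::floor(yc), k0 = (int)std::floor(zc);
  if (i0 > nx - 2) i0 = nx > 1 ? nx - 2 : 0;
  if (j0 > ny - 2) j0 = ny > 1 ? ny - 2 : 0;
  if (k0 > nz - 2) k0 = nz > 1 ? nz - 2 : 0;
  int i1 = nx > 1 ? i0 + 1 : i0, j1 = ny > 1 ? j0 + 1 : j0, k1 = nz > 1 ? k0 + 1 : k0;
  double fx = xc - i0, fy = yc - j0, fz = zc - k0;
  #define V(i,j,k) v[(i) + (size_t)nx * ((j) + (size_t)ny * (k))]
  double c00 = V(i0,j0,k0) * (1-fx) + V(i1,j0,k0) * fx;
  double c10 = V(i0,j1,k0) * (1-fx) + V(i1,j1,k0) * fx;
  double c01 = V(i0,j0,k1) * (1-fx) + V(i1,j0,k1) * fx;
  double c11 = V(i0,j1,k1) * (1-fx) + V(i1,j1,k1) * fx;
  #undef V
  double c0 = c00 * (1-fy) + c10 * fy;
  double c1 = c01 * (1-fy) + c11 * fy;
  return c0 * (1-fz) + c1 * fz;
}

// clamped trilinear sampling shared with the registration kernels
double sample_lin(const double *v, int nx, int ny, int nz,
                  double x, double y, double z) {
  return sample1(v, nx, ny, nz, x, y, z, true, true, 0.0);
}

// [[Rcpp::export]]
NumericVector cpp_sample_at(NumericVector src, IntegerVector sdim,
                            NumericMatrix coords, bool linear,
                            bool clamp, double fill) {
  int nx = sdim[0], ny = sdim[1], nz = sdim[2];
  R_xlen_t n = coords.nrow();
  NumericVector out(n);
  const double *v = src.begin();
  for (R_xlen_t t = 0; t < n; ++t)
    out[t] = sample1(v, nx, ny, nz, coords(t,0), coords(t,1), coords(t,2),
                     linear, clamp, fill);
  return out;
}

// Resample through a 3x4 affine M mapping output 0-based indices to
// source 0-based continuous indices.
// [[Rcpp::export]]
NumericVector cpp_resample_affine(NumericVector src, IntegerVector sdim,
                                  IntegerVector odim, NumericMatrix M,
                                  bool linear, bool clamp, double fill) {
  int nx = sdim[0], ny = sdim[1], nz = sdim[2];
  int ox = odim[0], oy = odim[1], oz = odim[2];
  NumericVector out((R_xlen_t)ox * oy * oz);
  const double *v = src.begin();
  double *o = out.begin();
  size_t t = 0;
  for (int k = 0; k < oz; ++k)
    for (int j = 0; j < oy; ++j)
      for (int i = 0; i < ox; ++i, ++t) {
        double x = M(0,0)*i + M(0,1)*j + M(0,2)*k + M(0,3);
        double y = M(1,0)*i + M(1,1)*j + M(1,2)*k + M(1,3);
        double z = M(2,0)*i + M(2,1)*j + M(2,2)*k + M(2,3);
        o[t] = sample1(v, nx, ny, nz, x, y, z, linear, clamp, fill);
      }
  out.attr("dim") = odim;
  return out;
}

// Warp a volume living on the same grid as the displacement field:
// out(x) = src(x + u(x)), u in voxel units (ux, uy, uz concatenated).
// [[Rcpp::export]]
NumericVector cpp_warp_same_grid(NumericVector src, IntegerVector dims,
                                 NumericVector ux, NumericVector uy,
                                 NumericVector uz, bool linear,
                                 bool clamp, double fill) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t n = (size_t)nx * ny * nz;
  NumericVector out((R_xlen_t)n);
  const double *v = src.begin();
  size_t t = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i, ++t)
        out[t] = sample1(v, nx, ny, nz, i + ux[t], j + uy[t], k + uz[t],
                         linear, clamp, fill);
  out.attr("dim") = dims;
  return out;
}

// Box-average downsampling by 2 along every axis.
// [[Rcpp::export]]
NumericVector cpp_downsample2(NumericVector src, IntegerVector sdim) {
  int nx = sdim[0], ny = sdim[1], nz = sdim[2];
  int ox = std::max(1, nx / 2), oy = std::max(1, ny / 2), oz = std::max(1, nz / 2);
  NumericVector out((R_xlen_t)ox * oy * oz);
  const double *v = src.begin();
  size_t t = 0;
  for (int k = 0; k < oz; ++k)
    for (int j = 0; j < oy; ++j)
      for (int i = 0; i < ox; ++i, ++t) {
        double s = 0; int c = 0;
        for (int dk = 0; dk < 2; ++dk)
          for (int dj = 0; dj < 2; ++dj)
            for (int di = 0; di < 2; ++di) {
              int ii = 2*i + di, jj = 2*j + dj, kk = 2*k + dk;
              if (ii < nx && jj < ny && kk < nz) {
                s += v[ii + (size_t)nx * (jj + (size_t)ny * kk)];
                ++c;
              }
            }
        out[t] = s / c;
      }
  out.attr("dim") = IntegerVector::create(ox, oy, oz);
  return out;
}
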