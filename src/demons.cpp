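#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

double sample_lin(const double *v, int nx, int ny, int nz,
                  double x, double y, double z);

static inline double clampd(double x, double lo, double hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

// Separable Gaussian smoothing (reflected boundary), sigma in voxels per axis.
static void gauss1d(std::vector<double> &kern, double sigma) {
  int r = std::max(1, (int)std::ceil(3.0 * sigma));
  kern.assign(2 * r + 1, 0.0);
  double s = 0;
  for (int i = -r; i <= r; ++i) {
    double w = std::exp(-0.5 * i * i / (sigma * sigma));
    kern[i + r] = w; s += w;
  }
  for (auto &w : kern) w /= s;
}

static void smooth_axis(double *v, double *tmp, int nx, int ny, int nz,
                        int axis, const std::vector<double> &kern) {
  int r = ((int)kern.size() - 1) / 2;
  int n[3] = {nx, ny, nz};
  size_t stride[3] = {1, (size_t)nx, (size_t)nx * ny};
  int na = n[axis];
  size_t sa = stride[axis];
  // iterate over all lines along `axis`
  int nb = axis == 0 ? ny : nx;
  int nc = axis == 2 ? ny : nz;
  size_t sb = axis == 0 ? stride[1] : stride[0];
  size_t sc = axis == 2 ? stride[1] : stride[2];
  std::vector<double> line(na);
  for (int c = 0; c < nc; ++c)
    for (int b = 0; b < nb; ++b) {
      size_t base = b * sb + c * sc;
      for (int a = 0; a < na; ++a) line[a] = v[base + a * sa];
      for (int a = 0; a < na; ++a) {
        double s = 0;
        for (int t = -r; t <= r; ++t) {
          int idx = a + t;
          if (idx < 0) idx = -idx - 1;          // reflect
          if (idx >= na) idx = 2 * na - idx - 1;
          if (idx < 0) idx = 0; if (idx >= na) idx = na - 1;
          s += kern[t + r] * line[idx];
        }
        v[base + a * sa] = s;
      }
    }
  (void)tmp;
}

void smooth3_inplace(double *v, int nx, int ny, int nz,
                     double sx, double sy, double sz) {
  std::vector<double> kern;
  if (sx > 0) { gauss1d(kern, sx); smooth_axis(v, nullptr, nx, ny, nz, 0, kern); }
  if (sy > 0) { gauss1d(kern, sy); smooth_axis(v, nullptr, nx, ny, nz, 1, kern); }
  if (sz > 0) { gauss1d(kern, sz); smooth_axis(v, nullptr, nx, ny, nz, 2, kern); }
}

// [[Rcpp::export]]
NumericVector cpp_smooth3(NumericVector src, IntegerVector dims,
                          NumericVector sigma) {
  NumericVector out = clone(src);
  smooth3_inplace(out.begin(), dims[0], dims[1], dims[2],
                  sigma[0], sigma[1], sigma[2]);
  out.attr("dim") = dims;
  return out;
}

static inline void grad_at(const double *v, int nx, int ny, int nz,
                           int i, int j, int k, double &gx, double &gy, double &gz) {
  #define V(i,j,k) v[(i) + (size_t)nx * ((j) + (size_t)ny * (k))]
  int ip = i < nx - 1 ? i + 1 : i, im = i > 0 ? i - 1 : i;
  int jp = j < ny - 1 ? j + 1 : j, jm = j > 0 ? j - 1 : j;
  int kp = k < nz - 1 ? k + 1 : k, km = k > 0 ? k - 1 : k;
  gx = (V(ip,j,k) - V(im,j,k)) / (ip - im > 0 ? ip - im : 1);
  gy = (V(i,jp,k) - V(i,jm,k)) / (jp - jm > 0 ? jp - jm : 1);
  gz = (V(i,j,kp) - V(i,j,km)) / (kp - km > 0 ? kp - km : 1);
  #undef V
}

// Single-level demons-style deformable registration on a common grid.
// fixed/moving: intensity volumes (already clipped/normalized by the caller).
// u0: optional initial displacement (voxel units), NULL for zeros.
// Returns the displacement field (voxel units), the accepted metric trace
// (mean squared difference, non-increasing), and a convergence flag.
// [[Rcpp::export]]
List cpp_demons_level(NumericVector fixed, NumericVector moving,
                      IntegerVector dims, Nullable<List> u0,
                      int max_iter, double sigma_fluid, double sigma_field,
                      double tol, double step0) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t n = (size_t)nx * ny * nz;
  std::vector<double> ux(n, 0), uy(n, 0), uz(n, 0);
  if (u0.isNotNull()) {
    List u = u0.get();
    NumericVector a = u[0], b = u[1], c = u[2];
    for (size_t t = 0; t < n; ++t) { ux[t] = a[t]; uy[t] = b[t]; uz[t] = c[t]; }
  }
  std::vector<double> bx = ux, by = uy, bz = uz;   // best-so-far field
  std::vector<double> warped(n), dux(n), duy(n), duz(n);
  const double *f = fixed.begin(), *m = moving.begin();
  std::vector<double> trace;
  double m_best = R_PosInf, step = step0;
  int fails = 0;
  bool converged = false;

  for (int iter = 0; iter < max_iter + 1; ++iter) {
    // evaluate current field
    size_t t = 0;
    double sse = 0;
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i, ++t) {
          double x = clampd(i + ux[t], 0, nx - 1);
          double y = clampd(j + uy[t], 0, ny - 1);
          double z = clampd(k + uz[t], 0, nz - 1);
          double w = sample_lin(m, nx, ny, nz, x, y, z);
          warped[t] = w;
          double d = w - f[t];
          sse += d * d;
        }
    double metric = sse / n;
    if (metric <= m_best * (1 + 1e-12)) {
      bool improved = (m_best - metric) > tol * (m_best > 0 ? m_best : 1.0);
      trace.push_back(metric);
      m_best = metric;
      bx = ux; by = uy; bz = uz;
      fails = 0;
      if (iter > 0 && !improved) { converged = true; break; }
    } else {
      ux = bx; uy = by; uz = bz;
      step *= 0.5;
      if (++fails > 2) break;
      // recompute warped for the reverted (best) field
      t = 0;
      for (int k = 0; k < nz; ++k)
        for (int j = 0; j < ny; ++j)
          for (int i = 0; i < nx; ++i, ++t) {
            double x = clampd(i + ux[t], 0, nx - 1);
            double y = clampd(j + uy[t], 0, ny - 1);
            double z = clampd(k + uz[t], 0, nz - 1);
            warped[t] = sample_lin(m, nx, ny, nz, x, y, z);
          }
    }
    if (iter == max_iter) break;

    // symmetric demons force
    t = 0;
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i, ++t) {
          double gfx, gfy, gfz, gwx, gwy, gwz;
          grad_at(f, nx, ny, nz, i, j, k, gfx, gfy, gfz);
          grad_at(warped.data(), nx, ny, nz, i, j, k, gwx, gwy, gwz);
          double jx = 0.5 * (gfx + gwx), jy = 0.5 * (gfy + gwy), jz = 0.5 * (gfz + gwz);
          double diff = f[t] - warped[t];
          double den = jx * jx + jy * jy + jz * jz + diff * diff;
          if (den < 1e-12) { dux[t] = duy[t] = duz[t] = 0; continue; }
          double g = step * diff / den;
          dux[t] = g * jx; duy[t] = g * jy; duz[t] = g * jz;
        }
    if (sigma_fluid > 0) {
      smooth3_inplace(dux.data(), nx, ny, nz, sigma_fluid, sigma_fluid, sigma_fluid);
      smooth3_inplace(duy.data(), nx, ny, nz, sigma_fluid, sigma_fluid, sigma_fluid);
      smooth3_inplace(duz.data(), nx, ny, nz, sigma_fluid, sigma_fluid, sigma_fluid);
    }
    for (size_t q = 0; q < n; ++q) { ux[q] += dux[q]; uy[q] += duy[q]; uz[q] += duz[q]; }
    if (sigma_field > 0) {
      smooth3_inplace(ux.data(), nx, ny, nz, sigma_field, sigma_field, sigma_field);
      smooth3_inplace(uy.data(), nx, ny, nz, sigma_field, sigma_field, sigma_field);
      smooth3_inplace(uz.data(), nx, ny, nz, sigma_field, sigma_field, sigma_field);
    }
  }

  NumericVector oux((R_xlen_t)n), ouy((R_xlen_t)n), ouz((R_xlen_t)n);
  for (size_t q = 0; q < n; ++q) { oux[q] = bx[q]; ouy[q] = by[q]; ouz[q] = bz[q]; }
  oux.attr("dim") = dims; ouy.attr("dim") = dims; ouz.attr("dim") = dims;
  return List::create(_["ux"] = oux, _["uy"] = ouy, _["uz"] = ouz,
                      _["trace"] = wrap(trace), _["converged"] = converged);
}

// Jacobian determinant of the mapping x -> x + u(x), u in voxel units.
// [[Rcpp::export]]
NumericVector cpp_jacobian_det(NumericVector ux, NumericVector uy,
                               NumericVector uz, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t n = (size_t)nx * ny * nz;
  NumericVector out((R_xlen_t)n);
  const double *pux = ux.begin(), *puy = uy.begin(), *puz = uz.begin();
  size_t t = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i, ++t) {
        double a[9];
        double gx, gy, gz;
        grad_at(pux, nx, ny, nz, i, j, k, gx, gy, gz);
        a[0] = 1 + gx; a[1] = gy; a[2] = gz;
        grad_at(puy, nx, ny, nz, i, j, k, gx, gy, gz);
        a[3] = gx; a[4] = 1 + gy; a[5] = gz;
        grad_at(puz, nx, ny, nz, i, j, k, gx, gy, gz);
        a[6] = gx; a[7] = gy; a[8] = 1 + gz;
        out[t] = a[0]*(a[4]*a[8]-a[5]*a[7]) - a[1]*(a[3]*a[8]-a[5]*a[6])
               + a[2]*(a[3]*a[7]-a[4]*a[6]);
      }
  out.attr("dim") = dims;
  return out;
}
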