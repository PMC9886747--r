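#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

void smooth3_inplace(double *v, int nx, int ny, int nz,
                     double sx, double sy, double sz);

// eigenvalues of a symmetric 3x3 matrix (analytic, trigonometric form)
static void eig3(double a11, double a22, double a33,
                 double a12, double a13, double a23,
                 double &e1, double &e2, double &e3) {
  double p1 = a12*a12 + a13*a13 + a23*a23;
  if (p1 < 1e-30) { e1 = a11; e2 = a22; e3 = a33; return; }
  double q = (a11 + a22 + a33) / 3.0;
  double p2 = (a11-q)*(a11-q) + (a22-q)*(a22-q) + (a33-q)*(a33-q) + 2*p1;
  double p = std::sqrt(p2 / 6.0);
  double b11 = (a11-q)/p, b22 = (a22-q)/p, b33 = (a33-q)/p;
  double b12 = a12/p, b13 = a13/p, b23 = a23/p;
  double detB = b11*(b22*b33 - b23*b23) - b12*(b12*b33 - b23*b13)
              + b13*(b12*b23 - b22*b13);
  double r = detB / 2.0;
  if (r < -1) r = -1; if (r > 1) r = 1;
  double phi = std::acos(r) / 3.0;
  e1 = q + 2*p*std::cos(phi);
  e3 = q + 2*p*std::cos(phi + 2.0*M_PI/3.0);
  e2 = 3*q - e1 - e3;
}

// Frangi-style tubular-structure score at one scale for bright structures.
// Returns scores in [0, 1]; the structureness cutoff c is cfrac times the
// maximum Frobenius norm of the scale-normalized Hessian over the volume.
// [[Rcpp::export]]
NumericVector cpp_frangi_scale(NumericVector src, IntegerVector dims,
                               NumericVector spacing, double sigma_mm,
                               double alpha, double beta, double cfrac) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t n = (size_t)nx * ny * nz;
  std::vector<double> sm(src.begin(), src.end());
  smooth3_inplace(sm.data(), nx, ny, nz,
                  sigma_mm / spacing[0], sigma_mm / spacing[1], sigma_mm / spacing[2]);
  double hx = spacing[0], hy = spacing[1], hz = spacing[2];
  std::vector<double> l1(n), l2(n), l3(n);
  double smax = 0;
  #define V(i,j,k) sm[(size_t)(i) + (size_t)nx * ((size_t)(j) + (size_t)ny * (size_t)(k))]
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        size_t t = i + (size_t)nx * (j + (size_t)ny * k);
        if (i == 0 || j == 0 || k == 0 || i == nx-1 || j == ny-1 || k == nz-1) {
          l1[t] = l2[t] = l3[t] = 0; continue;
        }
        double c = V(i,j,k);
        double hxx = (V(i+1,j,k) - 2*c + V(i-1,j,k)) / (hx*hx);
        double hyy = (V(i,j+1,k) - 2*c + V(i,j-1,k)) / (hy*hy);
        double hzz = (V(i,j,k+1) - 2*c + V(i,j,k-1)) / (hz*hz);
        double hxy = (V(i+1,j+1,k) - V(i+1,j-1,k) - V(i-1,j+1,k) + V(i-1,j-1,k)) / (4*hx*hy);
        double hxz = (V(i+1,j,k+1) - V(i+1,j,k-1) - V(i-1,j,k+1) + V(i-1,j,k-1)) / (4*hx*hz);
        double hyz = (V(i,j+1,k+1) - V(i,j+1,k-1) - V(i,j-1,k+1) + V(i,j-1,k-1)) / (4*hy*hz);
        double s2 = sigma_mm * sigma_mm;   // scale normalization (gamma = 2)
        double e1, e2, e3;
        eig3(s2*hxx, s2*hyy, s2*hzz, s2*hxy, s2*hxz, s2*hyz, e1, e2, e3);
        // sort by absolute value: |l1| <= |l2| <= |l3|
        double v[3] = {e1, e2, e3};
        for (int a = 0; a < 2; ++a)
          for (int b = 0; b < 2 - a; ++b)
            if (std::fabs(v[b]) > std::fabs(v[b+1])) std::swap(v[b], v[b+1]);
        l1[t] = v[0]; l2[t] = v[1]; l3[t] = v[2];
        double S = std::sqrt(v[0]*v[0] + v[1]*v[1] + v[2]*v[2]);
        if (S > smax) smax = S;
      }
  #undef V
  NumericVector out((R_xlen_t)n);
  double cnorm = cfrac * smax;
  if (cnorm < 1e-12) { out.attr("dim") = dims; return out; }  // flat volume
  for (size_t t = 0; t < n; ++t) {
    double L2 = l2[t], L3 = l3[t];
    if (L2 >= 0 || L3 >= 0) { out[t] = 0; continue; }   // bright tubes only
    double Ra = std::fabs(L2) / std::fabs(L3);
    double Rb = std::fabs(l1[t]) / std::sqrt(std::fabs(L2 * L3));
    double S = std::sqrt(l1[t]*l1[t] + L2*L2 + L3*L3);
    out[t] = (1 - std::exp(-Ra*Ra / (2*alpha*alpha)))
           * std::exp(-Rb*Rb / (2*beta*beta))
           * (1 - std::exp(-S*S / (2*cnorm*cnorm)));
  }
  out.attr("dim") = dims;
  return out;
}
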