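#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <queue>
#include <utility>
using namespace Rcpp;

// 26-connected component labeling (flood fill); labels 1..K in discovery order.
// [[Rcpp::export]]
IntegerVector cpp_cc26(LogicalVector mask, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t n = (size_t)nx * ny * nz;
  IntegerVector lab((R_xlen_t)n);
  int next = 0;
  std::vector<size_t> stack;
  for (size_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    lab[s] = ++next;
    stack.assign(1, s);
    while (!stack.empty()) {
      size_t t = stack.back(); stack.pop_back();
      int i = t % nx, j = (t / nx) % ny, k = t / ((size_t)nx * ny);
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (!di && !dj && !dk) continue;
            int ii = i + di, jj = j + dj, kk = k + dk;
            if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
              continue;
            size_t q = ii + (size_t)nx * (jj + (size_t)ny * kk);
            if (mask[q] && !lab[q]) { lab[q] = next; stack.push_back(q); }
          }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}

// Dijkstra shortest path on the 26-connected voxel grid.
// cost: per-voxel traversal cost (>= 0); edge weight = step length (mm)
// times the mean endpoint cost. Returns the minimal-cost path from start
// (0-based linear index) to the nearest target voxel.
// [[Rcpp::export]]
List cpp_dijkstra(NumericVector cost, IntegerVector dims,
                  NumericVector spacing, int start, LogicalVector target) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t n = (size_t)nx * ny * nz;
  std::vector<double> dist(n, R_PosInf);
  std::vector<int> parent(n, -1);
  typedef std::pair<double, size_t> QE;
  std::priority_queue<QE, std::vector<QE>, std::greater<QE> > pq;
  dist[start] = 0;
  pq.push(QE(0.0, (size_t)start));
  // precompute neighbor offsets and step lengths
  int off[26][3]; double slen[26]; int m = 0;
  for (int dk = -1; dk <= 1; ++dk)
    for (int dj = -1; dj <= 1; ++dj)
      for (int di = -1; di <= 1; ++di) {
        if (!di && !dj && !dk) continue;
        off[m][0] = di; off[m][1] = dj; off[m][2] = dk;
        double dx = di * spacing[0], dy = dj * spacing[1], dz = dk * spacing[2];
        slen[m] = std::sqrt(dx*dx + dy*dy + dz*dz);
        ++m;
      }
  long long found = -1;
  while (!pq.empty()) {
    QE top = pq.top(); pq.pop();
    size_t u = top.second;
    if (top.first > dist[u]) continue;
    if (target[u]) { found = (long long)u; break; }
    int i = u % nx, j = (u / nx) % ny, k = u / ((size_t)nx * ny);
    for (int e = 0; e < 26; ++e) {
      int ii = i + off[e][0], jj = j + off[e][1], kk = k + off[e][2];
      if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
        continue;
      size_t v = ii + (size_t)nx * (jj + (size_t)ny * kk);
      double w = dist[u] + slen[e] * 0.5 * (cost[u] + cost[v]);
      if (w < dist[v]) { dist[v] = w; parent[v] = (int)u; pq.push(QE(w, v)); }
    }
  }
  if (found < 0)
    return List::create(_["reached"] = false);
  std::vector<int> path;
  for (long long t = found; t >= 0; t = parent[t]) path.push_back((int)t);
  std::reverse(path.begin(), path.end());
  IntegerMatrix out(path.size(), 3);
  for (size_t t = 0; t < path.size(); ++t) {
    out(t, 0) = path[t] % nx;
    out(t, 1) = (path[t] / nx) % ny;
    out(t, 2) = path[t] / (nx * ny);
  }
  return List::create(_["reached"] = true, _["path"] = out,
                      _["cost"] = dist[found]);
}

// Max-composite a tube segment with Gaussian radial profile into `field`.
// p0/p1 are segment endpoints in 0-based voxel coordinates (isotropic-enough
// grids; distances evaluated in mm through `spacing`).
// [[Rcpp::export]]
NumericVector cpp_add_tube(NumericVector field, IntegerVector dims,
                           NumericVector spacing, NumericVector p0,
                           NumericVector p1, double sigma_mm, double peak) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector out = clone(field);
  double reach = 3.0 * sigma_mm;
  int lo[3], hi[3];
  for (int a = 0; a < 3; ++a) {
    double r = reach / spacing[a];
    lo[a] = std::max(0, (int)std::floor(std::min(p0[a], p1[a]) - r));
    hi[a] = std::min(dims[a] - 1, (int)std::ceil(std::max(p0[a], p1[a]) + r));
  }
  double dx = (p1[0]-p0[0]) * spacing[0], dy = (p1[1]-p0[1]) * spacing[1],
         dz = (p1[2]-p0[2]) * spacing[2];
  double L2 = dx*dx + dy*dy + dz*dz;
  for (int k = lo[2]; k <= hi[2]; ++k)
    for (int j = lo[1]; j <= hi[1]; ++j)
      for (int i = lo[0]; i <= hi[0]; ++i) {
        double qx = (i - p0[0]) * spacing[0], qy = (j - p0[1]) * spacing[1],
               qz = (k - p0[2]) * spacing[2];
        double s = L2 > 0 ? (qx*dx + qy*dy + qz*dz) / L2 : 0.0;
        if (s < 0) s = 0; if (s > 1) s = 1;
        double ex = qx - s*dx, ey = qy - s*dy, ez = qz - s*dz;
        double d2 = ex*ex + ey*ey + ez*ez;
        if (d2 > reach * reach) continue;
        double val = peak * std::exp(-0.5 * d2 / (sigma_mm * sigma_mm));
        size_t t = i + (size_t)nx * (j + (size_t)ny * k);
        if (val > out[t]) out[t] = val;
      }
  out.attr("dim") = dims;
  return out;
}

// Binary dilation by a metric radius in mm.
// [[Rcpp::export]]
LogicalVector cpp_dilate_mm(LogicalVector mask, IntegerVector dims,
                            NumericVector spacing, double radius_mm) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t n = (size_t)nx * ny * nz;
  LogicalVector out((R_xlen_t)n);
  int rx = (int)std::floor(radius_mm / spacing[0]);
  int ry = (int)std::floor(radius_mm / spacing[1]);
  int rz = (int)std::floor(radius_mm / spacing[2]);
  std::vector<int> offs;
  for (int dk = -rz; dk <= rz; ++dk)
    for (int dj = -ry; dj <= ry; ++dj)
      for (int di = -rx; di <= rx; ++di) {
        double d = std::sqrt(di*di*spacing[0]*spacing[0] +
                             dj*dj*spacing[1]*spacing[1] +
                             dk*dk*spacing[2]*spacing[2]);
        if (d <= radius_mm) { offs.push_back(di); offs.push_back(dj); offs.push_back(dk); }
      }
  for (size_t s = 0; s < n; ++s) {
    if (!mask[s]) continue;
    int i = s % nx, j = (s / nx) % ny, k = s / ((size_t)nx * ny);
    for (size_t o = 0; o < offs.size(); o += 3) {
      int ii = i + offs[o], jj = j + offs[o+1], kk = k + offs[o+2];
      if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
      out[ii + (size_t)nx * (jj + (size_t)ny * kk)] = true;
    }
  }
  out.attr("dim") = dims;
  return out;
}
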