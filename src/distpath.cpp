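#include <Rcpp.h>
#include <queue>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// Exact anisotropic Euclidean distance transform (Felzenszwalb &
// Huttenlocher lower-envelope 1D transform applied per axis). Returns,
// for every voxel, the distance (physical units) to the nearest
// background voxel centre; background voxels get 0. Values just inside
// the object are one voxel step from background, consistent with a
// centre-to-centre metric.
static void dt1d(const std::vector<double> &f, std::vector<double> &d,
                 double w2, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0; z[0] = -INFINITY; z[1] = INFINITY;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + w2 * q * q) - (f[v[k]] + w2 * v[k] * v[k])) /
          (2.0 * w2 * (q - v[k]));
      if (s <= z[k]) { --k; } else break;
    }
    ++k; v[k] = q; z[k] = s; z[k + 1] = INFINITY;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = q - v[k];
    d[q] = w2 * dq * dq + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericVector cpp_edt(LogicalVector mask, IntegerVector dims,
                      NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const double BIG = 1e30;
  std::vector<double> d(n);
  for (R_xlen_t i = 0; i < n; ++i) d[i] = mask[i] ? BIG : 0.0;
  const int strides[3] = {1, nx, nx * ny};
  const int sizes[3] = {nx, ny, nz};
  std::vector<double> line, out;
  for (int ax = 0; ax < 3; ++ax) {
    const int st = strides[ax], sz = sizes[ax];
    const double w2 = spacing[ax] * spacing[ax];
    const int oa = (ax + 1) % 3, ob = (ax + 2) % 3;
    line.resize(sz); out.resize(sz);
    for (int ib = 0; ib < sizes[ob]; ++ib)
      for (int ia = 0; ia < sizes[oa]; ++ia) {
        const R_xlen_t base =
            (R_xlen_t)ia * strides[oa] + (R_xlen_t)ib * strides[ob];
        for (int i = 0; i < sz; ++i) line[i] = d[base + (R_xlen_t)i * st];
        dt1d(line, out, w2, sz);
        for (int i = 0; i < sz; ++i) d[base + (R_xlen_t)i * st] = out[i];
      }
  }
  NumericVector res(n);
  for (R_xlen_t i = 0; i < n; ++i) res[i] = std::sqrt(d[i]);
  return res;
}

// Connected-component labelling of a logical mask. connectivity 6 or 26.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dims,
                                   int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<R_xlen_t> stack;
  int cur = 0;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    ++cur;
    stack.push_back(s);
    lab[s] = cur;
    while (!stack.empty()) {
      R_xlen_t p = stack.back(); stack.pop_back();
      int x = (int)(p % nx), y = (int)((p / nx) % ny), z = (int)(p / ((R_xlen_t)nx * ny));
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dx && !dy && !dz) continue;
            if (connectivity == 6 && std::abs(dx) + std::abs(dy) + std::abs(dz) > 1)
              continue;
            int qx = x + dx, qy = y + dy, qz = z + dz;
            if (qx < 0 || qy < 0 || qz < 0 || qx >= nx || qy >= ny || qz >= nz)
              continue;
            R_xlen_t q = (R_xlen_t)qx + (R_xlen_t)nx * (qy + (R_xlen_t)ny * qz);
            if (mask[q] && !lab[q]) { lab[q] = cur; stack.push_back(q); }
          }
    }
  }
  lab.attr("n") = cur;
  return lab;
}

struct QNode {
  double d; R_xlen_t v;
  bool operator<(const QNode &o) const { return d > o.d; }
};

// Dijkstra over the 26-connected voxel graph of a mask. Edge weight is
// the physical step length, optionally scaled by a medialness penalty
// 1/(0.5*(dt[a]+dt[b]) + eps)^2 so paths follow the medial axis.
// Returns distances and predecessors from `source`.
static void dijkstra(const LogicalVector &mask, const int *dims,
                     const double *spacing, const double *dtw, double eps,
                     R_xlen_t source, std::vector<double> &dist,
                     std::vector<R_xlen_t> &pred) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  dist.assign(n, INFINITY);
  pred.assign(n, -1);
  std::priority_queue<QNode> pq;
  dist[source] = 0.0;
  pq.push({0.0, source});
  while (!pq.empty()) {
    QNode t = pq.top(); pq.pop();
    if (t.d > dist[t.v]) continue;
    R_xlen_t p = t.v;
    int x = (int)(p % nx), y = (int)((p / nx) % ny), z = (int)(p / ((R_xlen_t)nx * ny));
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          if (!dx && !dy && !dz) continue;
          int qx = x + dx, qy = y + dy, qz = z + dz;
          if (qx < 0 || qy < 0 || qz < 0 || qx >= nx || qy >= ny || qz >= nz)
            continue;
          R_xlen_t q = (R_xlen_t)qx + (R_xlen_t)nx * (qy + (R_xlen_t)ny * qz);
          if (!mask[q]) continue;
          double sx = dx * spacing[0], sy = dy * spacing[1], sz2 = dz * spacing[2];
          double step = std::sqrt(sx * sx + sy * sy + sz2 * sz2);
          if (dtw) {
            double m = 0.5 * (dtw[p] + dtw[q]) + eps;
            step /= (m * m);
          }
          if (dist[p] + step < dist[q]) {
            dist[q] = dist[p] + step;
            pred[q] = p;
            pq.push({dist[q], q});
          }
        }
  }
}

static R_xlen_t farthest(const std::vector<double> &dist) {
  R_xlen_t best = -1; double bd = -1;
  for (R_xlen_t i = 0; i < (R_xlen_t)dist.size(); ++i)
    if (std::isfinite(dist[i]) && dist[i] > bd) { bd = dist[i]; best = i; }
  return best;
}

// Approximate geodesic-diameter path of a connected mask (double-sweep
// Dijkstra with the plain metric to find the endpoint pair, then an
// optionally medial-axis-weighted path between them). Returns the path
// as 0-based voxel indices (rows: x,y,z) plus its geometric arc length.
// [[Rcpp::export]]
List cpp_geodesic_path(LogicalVector mask, IntegerVector dims,
                       NumericVector spacing, NumericVector dtfield,
                       bool medial) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  R_xlen_t seed = -1;
  for (R_xlen_t i = 0; i < n; ++i) if (mask[i]) { seed = i; break; }
  if (seed < 0) stop("empty mask");
  int dims_i[3] = {nx, ny, nz};
  double sp[3] = {spacing[0], spacing[1], spacing[2]};
  std::vector<double> dist; std::vector<R_xlen_t> pred;
  dijkstra(mask, dims_i, sp, nullptr, 0, seed, dist, pred);
  R_xlen_t e1 = farthest(dist);
  dijkstra(mask, dims_i, sp, nullptr, 0, e1, dist, pred);
  R_xlen_t e2 = farthest(dist);
  const double *dtw = nullptr;
  double eps = 0.5 * std::min(sp[0], std::min(sp[1], sp[2]));
  if (medial && dtfield.size() == n) dtw = REAL(dtfield);
  if (dtw) dijkstra(mask, dims_i, sp, dtw, eps, e1, dist, pred);
  // walk back from e2 to e1
  std::vector<R_xlen_t> path;
  for (R_xlen_t v = e2; v != -1; v = pred[v]) path.push_back(v);
  std::reverse(path.begin(), path.end());
  const int m = (int)path.size();
  IntegerMatrix P(m, 3);
  double len = 0.0;
  for (int i = 0; i < m; ++i) {
    R_xlen_t p = path[i];
    P(i, 0) = (int)(p % nx);
    P(i, 1) = (int)((p / nx) % ny);
    P(i, 2) = (int)(p / ((R_xlen_t)nx * ny));
    if (i > 0) {
      double dx = (P(i, 0) - P(i - 1, 0)) * sp[0];
      double dy = (P(i, 1) - P(i - 1, 1)) * sp[1];
      double dz = (P(i, 2) - P(i - 1, 2)) * sp[2];
      len += std::sqrt(dx * dx + dy * dy + dz * dz);
    }
  }
  return List::create(_["path"] = P, _["length"] = len);
}
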