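#include <Rcpp.h>
#include <unordered_map>
#include <cstdint>
#include <cmath>
using namespace Rcpp;

// Separable 3D Gaussian blur on a double field stored in column-major
// (x fastest) order. sigma is per-axis in voxel units; sigma <= 0 skips
// that axis. Zero (background) boundary condition: callers pad crops.
// [[Rcpp::export]]
NumericVector cpp_gauss3(NumericVector field, IntegerVector dims,
                         NumericVector sigma) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<double> a(field.begin(), field.end()), b(n);
  const int strides[3] = {1, nx, nx * ny};
  const int sizes[3]   = {nx, ny, nz};
  for (int ax = 0; ax < 3; ++ax) {
    const double s = sigma[ax];
    if (s <= 0) continue;
    const int rad = (int)std::ceil(3.0 * s);
    std::vector<double> k(2 * rad + 1);
    double ksum = 0.0;
    for (int i = -rad; i <= rad; ++i) {
      k[i + rad] = std::exp(-0.5 * i * i / (s * s));
      ksum += k[i + rad];
    }
    for (double &v : k) v /= ksum;
    const int st = strides[ax], sz = sizes[ax];
    // iterate over all lines along axis ax
    const int oa = (ax + 1) % 3, ob = (ax + 2) % 3;
    for (int ib = 0; ib < sizes[ob]; ++ib) {
      for (int ia = 0; ia < sizes[oa]; ++ia) {
        const R_xlen_t base =
            (R_xlen_t)ia * strides[oa] + (R_xlen_t)ib * strides[ob];
        for (int i = 0; i < sz; ++i) {
          double acc = 0.0;
          const int lo = std::max(0, i - rad), hi = std::min(sz - 1, i + rad);
          for (int j = lo; j <= hi; ++j)
            acc += a[base + (R_xlen_t)j * st] * k[j - i + rad];
          b[base + (R_xlen_t)i * st] = acc;
        }
      }
    }
    std::swap(a, b);
  }
  return NumericVector(a.begin(), a.end());
}

// Iso-surface extraction by marching tetrahedra on the Kuhn 6-tet
// decomposition of each grid cube (consistent main diagonal, so shared
// faces between cubes triangulate identically and the welded mesh is
// watertight). Vertices are welded on grid edges. Triangle orientation
// is fixed so normals point from the inside (field > iso) outward.
// Coordinates: vertex_phys = (index + origin) * spacing, where `index`
// is the 0-based continuous voxel-node coordinate.
// [[Rcpp::export]]
List cpp_march_tets(NumericVector field, IntegerVector dims, double iso,
                    NumericVector spacing, NumericVector origin) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int64_t N = (int64_t)nx * ny * nz;
  auto idx = [&](int x, int y, int z) -> int64_t {
    return (int64_t)x + (int64_t)nx * ((int64_t)y + (int64_t)ny * z);
  };
  std::unordered_map<uint64_t, int> edge_vertex;
  edge_vertex.reserve(1 << 15);
  std::vector<double> VX, VY, VZ;
  std::vector<int> F; // triples of 0-based vertex ids

  // edge vertex: welded on the undirected pair of grid node ids
  auto get_vertex = [&](int64_t ga, int64_t gb, double va, double vb,
                        const int *ca, const int *cb) -> int {
    int64_t lo = ga < gb ? ga : gb, hi = ga < gb ? gb : ga;
    uint64_t key = (uint64_t)lo * (uint64_t)N + (uint64_t)hi;
    auto it = edge_vertex.find(key);
    if (it != edge_vertex.end()) return it->second;
    double t = (iso - va) / (vb - va);
    if (t < 0) t = 0; if (t > 1) t = 1;
    int id = (int)VX.size();
    VX.push_back(ca[0] + t * (cb[0] - ca[0]));
    VY.push_back(ca[1] + t * (cb[1] - ca[1]));
    VZ.push_back(ca[2] + t * (cb[2] - ca[2]));
    edge_vertex.emplace(key, id);
    return id;
  };

  // Kuhn decomposition around diagonal c0-c6 of the unit cube
  static const int cube_off[8][3] = {
      {0, 0, 0}, {1, 0, 0}, {1, 1, 0}, {0, 1, 0},
      {0, 0, 1}, {1, 0, 1}, {1, 1, 1}, {0, 1, 1}};
  static const int tets[6][4] = {{0, 1, 2, 6}, {0, 2, 3, 6}, {0, 3, 7, 6},
                                 {0, 7, 4, 6}, {0, 4, 5, 6}, {0, 5, 1, 6}};

  auto emit = [&](int a, int b, int c, const double in_c[3],
                  const double out_c[3]) {
    // orient so normal points from inside toward outside
    double ux = VX[b] - VX[a], uy = VY[b] - VY[a], uz = VZ[b] - VZ[a];
    double vx = VX[c] - VX[a], vy = VY[c] - VY[a], vz = VZ[c] - VZ[a];
    double nxn = uy * vz - uz * vy, nyn = uz * vx - ux * vz,
           nzn = ux * vy - uy * vx;
    double dx = out_c[0] - in_c[0], dy = out_c[1] - in_c[1],
           dz = out_c[2] - in_c[2];
    if (nxn * dx + nyn * dy + nzn * dz < 0) std::swap(b, c);
    F.push_back(a); F.push_back(b); F.push_back(c);
  };

  double corner_val[8];
  int corner_xyz[8][3];
  int64_t corner_gid[8];
  for (int z = 0; z < nz - 1; ++z)
    for (int y = 0; y < ny - 1; ++y)
      for (int x = 0; x < nx - 1; ++x) {
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; ++c) {
          int cx = x + cube_off[c][0], cy = y + cube_off[c][1],
              cz = z + cube_off[c][2];
          corner_xyz[c][0] = cx; corner_xyz[c][1] = cy; corner_xyz[c][2] = cz;
          corner_gid[c] = idx(cx, cy, cz);
          corner_val[c] = field[corner_gid[c]];
          (corner_val[c] > iso ? any_in : any_out) = true;
        }
        if (!any_in || !any_out) continue;
        for (int t = 0; t < 6; ++t) {
          int vin[4], vout[4], nin = 0, nout = 0;
          for (int c = 0; c < 4; ++c) {
            int cc = tets[t][c];
            if (corner_val[cc] > iso) vin[nin++] = cc; else vout[nout++] = cc;
          }
          if (nin == 0 || nin == 4) continue;
          double ic[3] = {0, 0, 0}, oc[3] = {0, 0, 0};
          for (int c = 0; c < nin; ++c)
            for (int d = 0; d < 3; ++d) ic[d] += corner_xyz[vin[c]][d];
          for (int c = 0; c < nout; ++c)
            for (int d = 0; d < 3; ++d) oc[d] += corner_xyz[vout[c]][d];
          for (int d = 0; d < 3; ++d) { ic[d] /= nin; oc[d] /= nout; }
          auto ev = [&](int a, int b) {
            return get_vertex(corner_gid[a], corner_gid[b], corner_val[a],
                              corner_val[b], corner_xyz[a], corner_xyz[b]);
          };
          if (nin == 1) {
            emit(ev(vin[0], vout[0]), ev(vin[0], vout[1]),
                 ev(vin[0], vout[2]), ic, oc);
          } else if (nin == 3) {
            emit(ev(vout[0], vin[0]), ev(vout[0], vin[1]),
                 ev(vout[0], vin[2]), ic, oc);
          } else { // nin == 2: quad ac-ad-bd-bc
            int ac = ev(vin[0], vout[0]), ad = ev(vin[0], vout[1]);
            int bc = ev(vin[1], vout[0]), bd = ev(vin[1], vout[1]);
            emit(ac, ad, bd, ic, oc);
            emit(ac, bd, bc, ic, oc);
          }
        }
      }

  const int nv = (int)VX.size(), nf = (int)(F.size() / 3);
  NumericMatrix V(nv, 3);
  for (int i = 0; i < nv; ++i) {
    V(i, 0) = (VX[i] + origin[0]) * spacing[0];
    V(i, 1) = (VY[i] + origin[1]) * spacing[1];
    V(i, 2) = (VZ[i] + origin[2]) * spacing[2];
  }
  IntegerMatrix Fm(nf, 3);
  for (int i = 0; i < nf; ++i) {
    Fm(i, 0) = F[3 * i] + 1; Fm(i, 1) = F[3 * i + 1] + 1;
    Fm(i, 2) = F[3 * i + 2] + 1;
  }
  return List::create(_["vertices"] = V, _["faces"] = Fm);
}

// Taubin lambda|mu smoothing with uniform (umbrella) Laplacian weights.
// Keeps the welded topology; callers re-impose the voxel-count volume
// afterwards by a normal-offset correction.
// [[Rcpp::export]]
NumericMatrix cpp_taubin(NumericMatrix V, IntegerMatrix F, int iters,
                         double lambda, double mu) {
  const int nv = V.nrow(), nf = F.nrow();
  // CSR adjacency (duplicate directed edges from the two incident
  // faces are removed after a counting-sort fill)
  const int *fa = INTEGER(F), *fb = fa + nf, *fc = fb + nf;
  std::vector<int> deg(nv + 1, 0), half(6 * nf);
  for (int i = 0; i < nf; ++i) {
    int a = fa[i] - 1, b = fb[i] - 1, c = fc[i] - 1;
    ++deg[a + 1]; ++deg[a + 1]; ++deg[b + 1]; ++deg[b + 1];
    ++deg[c + 1]; ++deg[c + 1];
  }
  for (int i = 0; i < nv; ++i) deg[i + 1] += deg[i];
  std::vector<int> fill(deg.begin(), deg.end());
  for (int i = 0; i < nf; ++i) {
    int a = fa[i] - 1, b = fb[i] - 1, c = fc[i] - 1;
    half[fill[a]++] = b; half[fill[a]++] = c;
    half[fill[b]++] = a; half[fill[b]++] = c;
    half[fill[c]++] = a; half[fill[c]++] = b;
  }
  std::vector<int> aptr(nv + 1), anbr; anbr.reserve(6 * nf / 2);
  for (int i = 0; i < nv; ++i) {
    aptr[i] = (int)anbr.size();
    std::sort(half.begin() + deg[i], half.begin() + deg[i + 1]);
    int prev = -1;
    for (int j = deg[i]; j < deg[i + 1]; ++j)
      if (half[j] != prev) { anbr.push_back(half[j]); prev = half[j]; }
  }
  aptr[nv] = (int)anbr.size();
  std::vector<double> X(nv), Y(nv), Z(nv), X2(nv), Y2(nv), Z2(nv);
  const double *vx = REAL(V), *vy = vx + nv, *vz = vy + nv;
  for (int i = 0; i < nv; ++i) { X[i] = vx[i]; Y[i] = vy[i]; Z[i] = vz[i]; }
  auto pass = [&](double f, std::vector<double> &x, std::vector<double> &y,
                  std::vector<double> &z, std::vector<double> &x2,
                  std::vector<double> &y2, std::vector<double> &z2) {
    for (int i = 0; i < nv; ++i) {
      const int lo = aptr[i], hi = aptr[i + 1];
      if (lo == hi) { x2[i] = x[i]; y2[i] = y[i]; z2[i] = z[i]; continue; }
      double mx = 0, my = 0, mz = 0;
      for (int j = lo; j < hi; ++j) {
        int q = anbr[j]; mx += x[q]; my += y[q]; mz += z[q];
      }
      const double k = 1.0 / (hi - lo);
      x2[i] = x[i] + f * (mx * k - x[i]);
      y2[i] = y[i] + f * (my * k - y[i]);
      z2[i] = z[i] + f * (mz * k - z[i]);
    }
  };
  for (int it = 0; it < iters; ++it) {
    pass(lambda, X, Y, Z, X2, Y2, Z2);
    pass(mu, X2, Y2, Z2, X, Y, Z);
  }
  NumericMatrix out(nv, 3);
  for (int i = 0; i < nv; ++i) {
    out(i, 0) = X[i]; out(i, 1) = Y[i]; out(i, 2) = Z[i];
  }
  return out;
}

// Area-weighted vertex normal accumulation (hot path of the
// volume-compensation step).
// [[Rcpp::export]]
NumericMatrix cpp_vertex_normals(NumericMatrix V, IntegerMatrix F) {
  const int nv = V.nrow(), nf = F.nrow();
  NumericMatrix N(nv, 3);
  const double *x = REAL(V), *y = x + nv, *z = y + nv;
  const int *fa = INTEGER(F), *fb = fa + nf, *fc = fb + nf;
  double *Nx = REAL(N), *Ny = Nx + nv, *Nz = Ny + nv;
  for (int i = 0; i < nf; ++i) {
    int a = fa[i] - 1, b = fb[i] - 1, c = fc[i] - 1;
    double ux = x[b] - x[a], uy = y[b] - y[a], uz = z[b] - z[a];
    double wx = x[c] - x[a], wy = y[c] - y[a], wz = z[c] - z[a];
    double nx = uy * wz - uz * wy, ny = uz * wx - ux * wz,
           nz = ux * wy - uy * wx;
    Nx[a] += nx; Ny[a] += ny; Nz[a] += nz;
    Nx[b] += nx; Ny[b] += ny; Nz[b] += nz;
    Nx[c] += nx; Ny[c] += ny; Nz[c] += nz;
  }
  for (int i = 0; i < nv; ++i) {
    double l = std::sqrt(Nx[i] * Nx[i] + Ny[i] * Ny[i] + Nz[i] * Nz[i]);
    if (l == 0) l = 1;
    Nx[i] /= l; Ny[i] /= l; Nz[i] /= l;
  }
  return N;
}

// Box-average k x k xy downsampling of a 3D field (z untouched); used
// to mesh large boutons at a coarser lateral grid. Output dims are
// ceil(nx/k), ceil(ny/k), nz; partial boxes average available samples.
// [[Rcpp::export]]
NumericVector cpp_downsample_xy(NumericVector field, IntegerVector dims,
                                int k) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int mx = (nx + k - 1) / k, my = (ny + k - 1) / k;
  NumericVector out((R_xlen_t)mx * my * nz);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < my; ++y)
      for (int x = 0; x < mx; ++x) {
        double s = 0; int c = 0;
        for (int dy = 0; dy < k; ++dy)
          for (int dx = 0; dx < k; ++dx) {
            int sx = k * x + dx, sy = k * y + dy;
            if (sx < nx && sy < ny) {
              s += field[(R_xlen_t)sx + (R_xlen_t)nx * (sy + (R_xlen_t)ny * z)];
              ++c;
            }
          }
        out[(R_xlen_t)x + (R_xlen_t)mx * (y + (R_xlen_t)my * z)] = s / c;
      }
  out.attr("dims") = IntegerVector::create(mx, my, nz);
  return out;
}

// Fused surface-area + signed-volume pass (hot path of the volume
// correction loop).
// [[Rcpp::export]]
NumericVector cpp_area_volume(NumericMatrix V, IntegerMatrix F) {
  const int nv = V.nrow(), nf = F.nrow();
  const double *x = REAL(V), *y = x + nv, *z = y + nv;
  const int *fa = INTEGER(F), *fb = fa + nf, *fc = fb + nf;
  double area = 0.0, vol = 0.0;
  for (int i = 0; i < nf; ++i) {
    int a = fa[i] - 1, b = fb[i] - 1, c = fc[i] - 1;
    double ux = x[b] - x[a], uy = y[b] - y[a], uz = z[b] - z[a];
    double wx = x[c] - x[a], wy = y[c] - y[a], wz = z[c] - z[a];
    double cx = uy * wz - uz * wy, cy = uz * wx - ux * wz,
           cz = ux * wy - uy * wx;
    area += std::sqrt(cx * cx + cy * cy + cz * cz);
    vol += x[a] * (y[b] * z[c] - z[b] * y[c]) -
           y[a] * (x[b] * z[c] - z[b] * x[c]) +
           z[a] * (x[b] * y[c] - y[b] * x[c]);
  }
  return NumericVector::create(area / 2.0, std::fabs(vol) / 6.0);
}
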