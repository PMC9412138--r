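// Computational kernels: surface voxelization (exact point-to-triangle
// distances), exact 3D squared Euclidean distance transform
// (Felzenszwalb-Huttenlocher lower-envelope algorithm), and 2D triangle
// rasterization for silhouette areas.

#include <Rcpp.h>
#include <cmath>
#include <limits>
#include <vector>

using namespace Rcpp;

// Closest-point-on-triangle squared distance (Ericson, Real-Time Collision
// Detection, 5.1.5).
static double point_tri_dist2(const double p[3], const double a[3],
                              const double b[3], const double c[3]) {
  double ab[3], ac[3], ap[3];
  for (int k = 0; k < 3; ++k) {
    ab[k] = b[k] - a[k];
    ac[k] = c[k] - a[k];
    ap[k] = p[k] - a[k];
  }
  double d1 = ab[0] * ap[0] + ab[1] * ap[1] + ab[2] * ap[2];
  double d2 = ac[0] * ap[0] + ac[1] * ap[1] + ac[2] * ap[2];
  if (d1 <= 0.0 && d2 <= 0.0) {
    return ap[0] * ap[0] + ap[1] * ap[1] + ap[2] * ap[2];
  }
  double bp[3];
  for (int k = 0; k < 3; ++k) bp[k] = p[k] - b[k];
  double d3 = ab[0] * bp[0] + ab[1] * bp[1] + ab[2] * bp[2];
  double d4 = ac[0] * bp[0] + ac[1] * bp[1] + ac[2] * bp[2];
  if (d3 >= 0.0 && d4 <= d3) {
    return bp[0] * bp[0] + bp[1] * bp[1] + bp[2] * bp[2];
  }
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double v = (d1 - d3 != 0.0) ? d1 / (d1 - d3) : 0.0;
    double q[3];
    for (int k = 0; k < 3; ++k) q[k] = a[k] + v * ab[k] - p[k];
    return q[0] * q[0] + q[1] * q[1] + q[2] * q[2];
  }
  double cp[3];
  for (int k = 0; k < 3; ++k) cp[k] = p[k] - c[k];
  double d5 = ab[0] * cp[0] + ab[1] * cp[1] + ab[2] * cp[2];
  double d6 = ac[0] * cp[0] + ac[1] * cp[1] + ac[2] * cp[2];
  if (d6 >= 0.0 && d5 <= d6) {
    return cp[0] * cp[0] + cp[1] * cp[1] + cp[2] * cp[2];
  }
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double w = (d2 - d6 != 0.0) ? d2 / (d2 - d6) : 0.0;
    double q[3];
    for (int k = 0; k < 3; ++k) q[k] = a[k] + w * ac[k] - p[k];
    return q[0] * q[0] + q[1] * q[1] + q[2] * q[2];
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double denom = (d4 - d3) + (d5 - d6);
    double w = (denom != 0.0) ? (d4 - d3) / denom : 0.0;
    double q[3];
    for (int k = 0; k < 3; ++k)
      q[k] = b[k] + w * (c[k] - b[k]) - p[k];
    return q[0] * q[0] + q[1] * q[1] + q[2] * q[2];
  }
  double denom = va + vb + vc;
  double v = vb / denom, w = vc / denom;
  double q[3];
  for (int k = 0; k < 3; ++k) q[k] = a[k] + ab[k] * v + ac[k] * w - p[k];
  return q[0] * q[0] + q[1] * q[1] + q[2] * q[2];
}

// Mark every voxel whose centre lies within spacing/2 of the mesh surface.
// Voxel centres sit at origin + (index + 0.5) * spacing (0-based index).
// [[Rcpp::export]]
LogicalVector voxelize_tris_cpp(NumericMatrix V, IntegerMatrix F,
                                NumericVector origin, double spacing,
                                IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t total = (R_xlen_t)nx * ny * nz;
  LogicalVector occ(total, false);
  const double half = spacing / 2.0;
  const double thr2 = half * half * (1.0 + 1e-12);
  const int nf = F.nrow();

  for (int t = 0; t < nf; ++t) {
    double a[3], b[3], c[3];
    for (int k = 0; k < 3; ++k) {
      a[k] = V(F(t, 0) - 1, k);
      b[k] = V(F(t, 1) - 1, k);
      c[k] = V(F(t, 2) - 1, k);
    }
    int lo[3], hi[3];
    for (int k = 0; k < 3; ++k) {
      double mn = std::min(a[k], std::min(b[k], c[k])) - half;
      double mx = std::max(a[k], std::max(b[k], c[k])) + half;
      lo[k] = (int)std::floor((mn - origin[k]) / spacing - 0.5);
      hi[k] = (int)std::ceil((mx - origin[k]) / spacing - 0.5);
      int lim = (k == 0 ? nx : (k == 1 ? ny : nz)) - 1;
      if (lo[k] < 0) lo[k] = 0;
      if (hi[k] > lim) hi[k] = lim;
    }
    for (int iz = lo[2]; iz <= hi[2]; ++iz) {
      for (int iy = lo[1]; iy <= hi[1]; ++iy) {
        R_xlen_t base = (R_xlen_t)iz * nx * ny + (R_xlen_t)iy * nx;
        for (int ix = lo[0]; ix <= hi[0]; ++ix) {
          R_xlen_t idx = base + ix;
          if (occ[idx]) continue;
          double p[3] = {origin[0] + (ix + 0.5) * spacing,
                         origin[1] + (iy + 0.5) * spacing,
                         origin[2] + (iz + 0.5) * spacing};
          if (point_tri_dist2(p, a, b, c) <= thr2) occ[idx] = true;
        }
      }
    }
  }
  return occ;
}

// 1D squared-distance transform (lower envelope of parabolas).  The caller
// guarantees at least one finite entry; infinite entries (no source yet)
// simply contribute no parabola.
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z, int n) {
  const double INF = std::numeric_limits<double>::infinity();
  int q0 = 0;
  while (f[q0] == INF) ++q0;
  int k = 0;
  v[0] = q0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = q0 + 1; q < n; ++q) {
    if (f[q] == INF) continue;
    double s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
               (2.0 * (q - v[k]));
    while (s <= z[k]) {
      --k;
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * (q - v[k]));
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Exact squared Euclidean distance (in voxel units) from every voxel centre
// to the nearest occupied voxel centre.
// [[Rcpp::export]]
NumericVector edt3d_sq_cpp(LogicalVector occ, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t total = (R_xlen_t)nx * ny * nz;
  const double INF = std::numeric_limits<double>::infinity();
  NumericVector d(total);
  for (R_xlen_t i = 0; i < total; ++i) d[i] = occ[i] ? 0.0 : INF;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), out(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along x
  for (int iz = 0; iz < nz; ++iz) {
    for (int iy = 0; iy < ny; ++iy) {
      R_xlen_t base = (R_xlen_t)iz * nx * ny + (R_xlen_t)iy * nx;
      bool any = false;
      for (int ix = 0; ix < nx; ++ix) {
        f[ix] = d[base + ix];
        if (f[ix] < INF) any = true;
      }
      if (!any) continue;
      dt1d(f, out, v, z, nx);
      for (int ix = 0; ix < nx; ++ix) d[base + ix] = out[ix];
    }
  }
  // pass along y
  for (int iz = 0; iz < nz; ++iz) {
    for (int ix = 0; ix < nx; ++ix) {
      R_xlen_t base = (R_xlen_t)iz * nx * ny + ix;
      bool any = false;
      for (int iy = 0; iy < ny; ++iy) {
        f[iy] = d[base + (R_xlen_t)iy * nx];
        if (f[iy] < INF) any = true;
      }
      if (!any) continue;
      dt1d(f, out, v, z, ny);
      for (int iy = 0; iy < ny; ++iy) d[base + (R_xlen_t)iy * nx] = out[iy];
    }
  }
  // pass along z
  const R_xlen_t slab = (R_xlen_t)nx * ny;
  for (int iy = 0; iy < ny; ++iy) {
    for (int ix = 0; ix < nx; ++ix) {
      R_xlen_t base = (R_xlen_t)iy * nx + ix;
      bool any = false;
      for (int iz = 0; iz < nz; ++iz) {
        f[iz] = d[base + (R_xlen_t)iz * slab];
        if (f[iz] < INF) any = true;
      }
      if (!any) continue;
      dt1d(f, out, v, z, nz);
      for (int iz = 0; iz < nz; ++iz) d[base + (R_xlen_t)iz * slab] = out[iz];
    }
  }
  return d;
}

// Count pixels whose centre is covered by at least one projected triangle
// (overlaps counted once).  P holds projected 2D vertex coordinates.
// [[Rcpp::export]]
double rasterize_tris_cpp(NumericMatrix P, IntegerMatrix F,
                          NumericVector origin, double pixel,
                          IntegerVector dims) {
  const int nx = dims[0], ny = dims[1];
  const R_xlen_t total = (R_xlen_t)nx * ny;
  std::vector<char> covered(total, 0);
  const int nf = F.nrow();

  for (int t = 0; t < nf; ++t) {
    double ax = P(F(t, 0) - 1, 0), ay = P(F(t, 0) - 1, 1);
    double bx = P(F(t, 1) - 1, 0), by = P(F(t, 1) - 1, 1);
    double cx = P(F(t, 2) - 1, 0), cy = P(F(t, 2) - 1, 1);
    double area2 = (bx - ax) * (cy - ay) - (by - ay) * (cx - ax);
    if (area2 == 0.0) continue;  // edge-on sliver: contributes no area
    if (area2 < 0.0) {           // enforce CCW winding
      std::swap(bx, cx);
      std::swap(by, cy);
      area2 = -area2;
    }
    double tol = 1e-9 * area2;
    double mnx = std::min(ax, std::min(bx, cx));
    double mxx = std::max(ax, std::max(bx, cx));
    double mny = std::min(ay, std::min(by, cy));
    double mxy = std::max(ay, std::max(by, cy));
    int ix0 = std::max(0, (int)std::floor((mnx - origin[0]) / pixel - 0.5));
    int ix1 = std::min(nx - 1, (int)std::ceil((mxx - origin[0]) / pixel - 0.5));
    int iy0 = std::max(0, (int)std::floor((mny - origin[1]) / pixel - 0.5));
    int iy1 = std::min(ny - 1, (int)std::ceil((mxy - origin[1]) / pixel - 0.5));
    for (int iy = iy0; iy <= iy1; ++iy) {
      double py = origin[1] + (iy + 0.5) * pixel;
      R_xlen_t base = (R_xlen_t)iy * nx;
      for (int ix = ix0; ix <= ix1; ++ix) {
        R_xlen_t idx = base + ix;
        if (covered[idx]) continue;
        double px = origin[0] + (ix + 0.5) * pixel;
        double e1 = (bx - ax) * (py - ay) - (by - ay) * (px - ax);
        if (e1 < -tol) continue;
        double e2 = (cx - bx) * (py - by) - (cy - by) * (px - bx);
        if (e2 < -tol) continue;
        double e3 = (ax - cx) * (py - cy) - (ay - cy) * (px - cx);
        if (e3 < -tol) continue;
        covered[idx] = 1;
      }
    }
  }
  R_xlen_t count = 0;
  for (R_xlen_t i = 0; i < total; ++i) count += covered[i];
  return (double)count;
}
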