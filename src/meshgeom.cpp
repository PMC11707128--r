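// Mesh/grid geometry kernels: triangle-box overlap (separating axis test)
// for surface voxelization, parity ray casting for inside/outside queries,
// and exact point-to-triangle distance with a uniform-grid accelerator.
// All coordinates in mm; faces are 1-based on entry (R convention).
#include <Rcpp.h>
#include <cstdint>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

namespace {

struct V3 { double x, y, z; };
static inline V3 v3(double x, double y, double z) { V3 v; v.x = x; v.y = y; v.z = z; return v; }
static inline V3 sub(const V3& a, const V3& b) { return v3(a.x - b.x, a.y - b.y, a.z - b.z); }
static inline V3 cross(const V3& a, const V3& b) {
  return v3(a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x);
}
static inline double dot(const V3& a, const V3& b) { return a.x * b.x + a.y * b.y + a.z * b.z; }

// Akenine-Moller triangle/AABB overlap; box given by center and half sizes.
static bool tri_box_overlap(const V3& c, const V3& h, V3 t0, V3 t1, V3 t2) {
  t0 = sub(t0, c); t1 = sub(t1, c); t2 = sub(t2, c);
  V3 e0 = sub(t1, t0), e1 = sub(t2, t1), e2 = sub(t0, t2);
  double p0, p1, p2, rad, mn, mx;
#define AXTEST(a, b, fa, fb, va, vb, ca, cb, ha, hb)            \
  p0 = (a) * (va).ca - (b) * (va).cb;                           \
  p1 = (a) * (vb).ca - (b) * (vb).cb;                           \
  if (p0 < p1) { mn = p0; mx = p1; } else { mn = p1; mx = p0; } \
  rad = (fa) * (h).ha + (fb) * (h).hb;                          \
  if (mn > rad || mx < -rad) return false;
  double fex, fey, fez;
  fex = std::fabs(e0.x); fey = std::fabs(e0.y); fez = std::fabs(e0.z);
  AXTEST(e0.z, e0.y, fez, fey, t0, t2, y, z, y, z)
  AXTEST(e0.z, e0.x, fez, fex, t0, t2, x, z, x, z)
  AXTEST(e0.y, e0.x, fey, fex, t1, t2, x, y, x, y)
  fex = std::fabs(e1.x); fey = std::fabs(e1.y); fez = std::fabs(e1.z);
  AXTEST(e1.z, e1.y, fez, fey, t0, t2, y, z, y, z)
  AXTEST(e1.z, e1.x, fez, fex, t0, t2, x, z, x, z)
  AXTEST(e1.y, e1.x, fey, fex, t0, t1, x, y, x, y)
  fex = std::fabs(e2.x); fey = std::fabs(e2.y); fez = std::fabs(e2.z);
  AXTEST(e2.z, e2.y, fez, fey, t0, t1, y, z, y, z)
  AXTEST(e2.z, e2.x, fez, fex, t0, t1, x, z, x, z)
  AXTEST(e2.y, e2.x, fey, fex, t1, t2, x, y, x, y)
#undef AXTEST
  mn = std::min(t0.x, std::min(t1.x, t2.x)); mx = std::max(t0.x, std::max(t1.x, t2.x));
  if (mn > h.x || mx < -h.x) return false;
  mn = std::min(t0.y, std::min(t1.y, t2.y)); mx = std::max(t0.y, std::max(t1.y, t2.y));
  if (mn > h.y || mx < -h.y) return false;
  mn = std::min(t0.z, std::min(t1.z, t2.z)); mx = std::max(t0.z, std::max(t1.z, t2.z));
  if (mn > h.z || mx < -h.z) return false;
  V3 n = cross(e0, e1);
  double d = -dot(n, t0);
  double r = h.x * std::fabs(n.x) + h.y * std::fabs(n.y) + h.z * std::fabs(n.z);
  double s = -d;  // n . boxcenter(=origin) + d
  if (std::fabs(s) > r) return false;
  return true;
}

// squared distance from point p to triangle (a, b, c) -- Ericson, RTCD 5.1.5
static double pt_tri_d2(const V3& p, const V3& a, const V3& b, const V3& c) {
  V3 ab = sub(b, a), ac = sub(c, a), ap = sub(p, a);
  double d1 = dot(ab, ap), d2 = dot(ac, ap);
  if (d1 <= 0 && d2 <= 0) { return dot(ap, ap); }
  V3 bp = sub(p, b);
  double d3 = dot(ab, bp), d4 = dot(ac, bp);
  if (d3 >= 0 && d4 <= d3) { return dot(bp, bp); }
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    double t = d1 / (d1 - d3);
    V3 q = v3(a.x + t * ab.x, a.y + t * ab.y, a.z + t * ab.z);
    V3 d = sub(p, q); return dot(d, d);
  }
  V3 cp = sub(p, c);
  double d5 = dot(ab, cp), d6 = dot(ac, cp);
  if (d6 >= 0 && d5 <= d6) { return dot(cp, cp); }
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    double t = d2 / (d2 - d6);
    V3 q = v3(a.x + t * ac.x, a.y + t * ac.y, a.z + t * ac.z);
    V3 d = sub(p, q); return dot(d, d);
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    double t = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    V3 q = v3(b.x + t * (c.x - b.x), b.y + t * (c.y - b.y), b.z + t * (c.z - b.z));
    V3 d = sub(p, q); return dot(d, d);
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  V3 q = v3(a.x + ab.x * v + ac.x * w, a.y + ab.y * v + ac.y * w, a.z + ab.z * v + ac.z * w);
  V3 d = sub(p, q); return dot(d, d);
}

// does the +x ray from (ry, rz) cross triangle t0 t1 t2, and where?
static bool ray_x_hit(double ry, double rz, const V3& t0, const V3& t1, const V3& t2,
                      double& xhit) {
  // 2D edge-function point-in-triangle in the (y, z) projection
  double ay = t0.y - ry, az = t0.z - rz;
  double by = t1.y - ry, bz = t1.z - rz;
  double cy = t2.y - ry, cz = t2.z - rz;
  double u = by * cz - bz * cy;
  double v = cy * az - cz * ay;
  double w = ay * bz - az * by;
  if (!((u > 0 && v > 0 && w > 0) || (u < 0 && v < 0 && w < 0))) return false;
  double s = u + v + w;
  xhit = (u * t0.x + v * t1.x + w * t2.x) / s;
  return true;
}

struct TriSoup {
  std::vector<V3> a, b, c;
  int n;
  TriSoup(const NumericMatrix& Vm, const IntegerMatrix& Fm) {
    n = Fm.nrow();
    a.resize(n); b.resize(n); c.resize(n);
    for (int f = 0; f < n; ++f) {
      int i0 = Fm(f, 0) - 1, i1 = Fm(f, 1) - 1, i2 = Fm(f, 2) - 1;
      a[f] = v3(Vm(i0, 0), Vm(i0, 1), Vm(i0, 2));
      b[f] = v3(Vm(i1, 0), Vm(i1, 1), Vm(i1, 2));
      c[f] = v3(Vm(i2, 0), Vm(i2, 1), Vm(i2, 2));
    }
  }
};

// deterministic sub-voxel jitter keeping rays off triangle edges
const double JY = 0.3419876243e-3, JZ = 0.7093318581e-3;

}  // namespace

// Surface voxels: voxel boxes [center +/- spacing/2] with positive-measure
// triangle overlap (boxes shrunk by a tiny epsilon so exact touching does
// not count).
// [[Rcpp::export(name = ".cs_surface_voxels")]]
LogicalVector cs_surface_voxels(const NumericMatrix& Vm, const IntegerMatrix& Fm,
                                const IntegerVector& dims, const NumericVector& sp,
                                const NumericVector& org) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  TriSoup T(Vm, Fm);
  LogicalVector out((R_xlen_t)nx * ny * nz);
  const double eps = 1e-9 * std::max(sp[0], std::max(sp[1], sp[2]));
  V3 h = v3(sp[0] / 2 - eps, sp[1] / 2 - eps, sp[2] / 2 - eps);
  for (int f = 0; f < T.n; ++f) {
    double bx0 = std::min(T.a[f].x, std::min(T.b[f].x, T.c[f].x));
    double bx1 = std::max(T.a[f].x, std::max(T.b[f].x, T.c[f].x));
    double by0 = std::min(T.a[f].y, std::min(T.b[f].y, T.c[f].y));
    double by1 = std::max(T.a[f].y, std::max(T.b[f].y, T.c[f].y));
    double bz0 = std::min(T.a[f].z, std::min(T.b[f].z, T.c[f].z));
    double bz1 = std::max(T.a[f].z, std::max(T.b[f].z, T.c[f].z));
    int i0 = std::max(0, (int)std::ceil((bx0 - org[0]) / sp[0] - 0.5 - 1e-9));
    int i1 = std::min(nx - 1, (int)std::floor((bx1 - org[0]) / sp[0] + 0.5 + 1e-9));
    int j0 = std::max(0, (int)std::ceil((by0 - org[1]) / sp[1] - 0.5 - 1e-9));
    int j1 = std::min(ny - 1, (int)std::floor((by1 - org[1]) / sp[1] + 0.5 + 1e-9));
    int k0 = std::max(0, (int)std::ceil((bz0 - org[2]) / sp[2] - 0.5 - 1e-9));
    int k1 = std::min(nz - 1, (int)std::floor((bz1 - org[2]) / sp[2] + 0.5 + 1e-9));
    for (int k = k0; k <= k1; ++k)
      for (int j = j0; j <= j1; ++j)
        for (int i = i0; i <= i1; ++i) {
          R_xlen_t m = (R_xlen_t)i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
          if (out[m]) continue;
          V3 ctr = v3(org[0] + i * sp[0], org[1] + j * sp[1], org[2] + k * sp[2]);
          if (tri_box_overlap(ctr, h, T.a[f], T.b[f], T.c[f])) out[m] = true;
        }
  }
  return out;
}

// Voxel centers strictly inside the mesh (parity of +x ray crossings).
// [[Rcpp::export(name = ".cs_grid_inside")]]
LogicalVector cs_grid_inside(const NumericMatrix& Vm, const IntegerMatrix& Fm,
                             const IntegerVector& dims, const NumericVector& sp,
                             const NumericVector& org) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  TriSoup T(Vm, Fm);
  LogicalVector out((R_xlen_t)nx * ny * nz);
  const double jy = JY * sp[1], jz = JZ * sp[2];
  std::vector<std::vector<double>> hits((size_t)ny * nz);
  for (int f = 0; f < T.n; ++f) {
    double by0 = std::min(T.a[f].y, std::min(T.b[f].y, T.c[f].y));
    double by1 = std::max(T.a[f].y, std::max(T.b[f].y, T.c[f].y));
    double bz0 = std::min(T.a[f].z, std::min(T.b[f].z, T.c[f].z));
    double bz1 = std::max(T.a[f].z, std::max(T.b[f].z, T.c[f].z));
    int j0 = std::max(0, (int)std::ceil((by0 - org[1] - jy) / sp[1] - 1e-12));
    int j1 = std::min(ny - 1, (int)std::floor((by1 - org[1] - jy) / sp[1] + 1e-12));
    int k0 = std::max(0, (int)std::ceil((bz0 - org[2] - jz) / sp[2] - 1e-12));
    int k1 = std::min(nz - 1, (int)std::floor((bz1 - org[2] - jz) / sp[2] + 1e-12));
    for (int k = k0; k <= k1; ++k)
      for (int j = j0; j <= j1; ++j) {
        double ry = org[1] + j * sp[1] + jy, rz = org[2] + k * sp[2] + jz;
        double xh;
        if (ray_x_hit(ry, rz, T.a[f], T.b[f], T.c[f], xh))
          hits[(size_t)j + (size_t)ny * k].push_back(xh);
      }
  }
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      std::vector<double>& h = hits[(size_t)j + (size_t)ny * k];
      if (h.empty()) continue;
      std::sort(h.begin(), h.end());
      size_t pos = 0;
      for (int i = 0; i < nx; ++i) {
        double xc = org[0] + i * sp[0];
        while (pos < h.size() && h[pos] < xc) ++pos;
        if (pos & 1) out[(R_xlen_t)i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)] = true;
      }
    }
  return out;
}

// [[Rcpp::export(name = ".cs_points_in_mesh")]]
LogicalVector cs_points_in_mesh(const NumericMatrix& P, const NumericMatrix& Vm,
                                const IntegerMatrix& Fm) {
  TriSoup T(Vm, Fm);
  const int np = P.nrow();
  LogicalVector out(np);
  double scale = 0;
  for (int f = 0; f < T.n; ++f) scale = std::max(scale, std::fabs(T.a[f].y) + std::fabs(T.a[f].z));
  const double jy = JY * (scale + 1) * 1e-3, jz = JZ * (scale + 1) * 1e-3;
  for (int p = 0; p < np; ++p) {
    double ry = P(p, 1) + jy, rz = P(p, 2) + jz, px = P(p, 0);
    int cnt = 0;
    double xh;
    for (int f = 0; f < T.n; ++f)
      if (ray_x_hit(ry, rz, T.a[f], T.b[f], T.c[f], xh) && xh > px) ++cnt;
    out[p] = (cnt & 1) != 0;
  }
  return out;
}

// Exact distances from query points to a triangle mesh, uniform-grid search.
// [[Rcpp::export(name = ".cs_point_mesh_dist")]]
NumericVector cs_point_mesh_dist(const NumericMatrix& P, const NumericMatrix& Vm,
                                 const IntegerMatrix& Fm) {
  TriSoup T(Vm, Fm);
  const int np = P.nrow();
  NumericVector out(np);
  if (T.n == 0) { std::fill(out.begin(), out.end(), NA_REAL); return out; }
  double lo[3] = {1e300, 1e300, 1e300}, hi[3] = {-1e300, -1e300, -1e300};
  for (int f = 0; f < T.n; ++f) {
    const V3* vs[3] = {&T.a[f], &T.b[f], &T.c[f]};
    for (int s = 0; s < 3; ++s) {
      const double q[3] = {vs[s]->x, vs[s]->y, vs[s]->z};
      for (int d = 0; d < 3; ++d) { lo[d] = std::min(lo[d], q[d]); hi[d] = std::max(hi[d], q[d]); }
    }
  }
  int gd[3];
  double h[3];
  double diag = 0;
  for (int d = 0; d < 3; ++d) diag += (hi[d] - lo[d]) * (hi[d] - lo[d]);
  diag = std::sqrt(std::max(diag, 1e-12));
  int target = std::max(4, (int)std::cbrt((double)T.n));
  for (int d = 0; d < 3; ++d) {
    double ext = std::max(hi[d] - lo[d], 1e-9 * diag);
    gd[d] = std::min(96, std::max(1, (int)(target * ext / (diag / std::sqrt(3.0)))));
    h[d] = ext / gd[d] * (1 + 1e-12);
  }
  double hmin = std::min(h[0], std::min(h[1], h[2]));
  std::vector<std::vector<int>> cells((size_t)gd[0] * gd[1] * gd[2]);
  for (int f = 0; f < T.n; ++f) {
    double b0[3] = {std::min(T.a[f].x, std::min(T.b[f].x, T.c[f].x)),
                    std::min(T.a[f].y, std::min(T.b[f].y, T.c[f].y)),
                    std::min(T.a[f].z, std::min(T.b[f].z, T.c[f].z))};
    double b1[3] = {std::max(T.a[f].x, std::max(T.b[f].x, T.c[f].x)),
                    std::max(T.a[f].y, std::max(T.b[f].y, T.c[f].y)),
                    std::max(T.a[f].z, std::max(T.b[f].z, T.c[f].z))};
    int c0[3], c1[3];
    for (int d = 0; d < 3; ++d) {
      c0[d] = std::min(gd[d] - 1, std::max(0, (int)((b0[d] - lo[d]) / h[d])));
      c1[d] = std::min(gd[d] - 1, std::max(0, (int)((b1[d] - lo[d]) / h[d])));
    }
    for (int k = c0[2]; k <= c1[2]; ++k)
      for (int j = c0[1]; j <= c1[1]; ++j)
        for (int i = c0[0]; i <= c1[0]; ++i)
          cells[(size_t)i + (size_t)gd[0] * (j + (size_t)gd[1] * k)].push_back(f);
  }
  std::vector<int> stamp((size_t)T.n, -1);
  for (int p = 0; p < np; ++p) {
    V3 q = v3(P(p, 0), P(p, 1), P(p, 2));
    double qc[3] = {q.x, q.y, q.z};
    int cc[3];
    double dout = 0;
    for (int d = 0; d < 3; ++d) {
      double t = (qc[d] - lo[d]) / h[d];
      cc[d] = std::min(gd[d] - 1, std::max(0, (int)t));
      double excess = std::max(0.0, std::max(lo[d] - qc[d], qc[d] - hi[d]));
      dout = std::max(dout, excess);
    }
    double best = 1e300;
    int maxL = gd[0] + gd[1] + gd[2];
    for (int L = 0; L <= maxL; ++L) {
      double lb = std::max((L - 1) * hmin, dout);
      if (lb * lb > best) break;
      int i0 = cc[0] - L, i1 = cc[0] + L;
      int j0 = cc[1] - L, j1 = cc[1] + L;
      int k0 = cc[2] - L, k1 = cc[2] + L;
      for (int k = std::max(0, k0); k <= std::min(gd[2] - 1, k1); ++k)
        for (int j = std::max(0, j0); j <= std::min(gd[1] - 1, j1); ++j)
          for (int i = std::max(0, i0); i <= std::min(gd[0] - 1, i1); ++i) {
            if (L > 0 && i != i0 && i != i1 && j != j0 && j != j1 && k != k0 && k != k1)
              continue;  // interior of the ring, already visited
            const std::vector<int>& cell = cells[(size_t)i + (size_t)gd[0] * (j + (size_t)gd[1] * k)];
            for (size_t s = 0; s < cell.size(); ++s) {
              int f = cell[s];
              if (stamp[f] == p) continue;
              stamp[f] = p;
              double d2 = pt_tri_d2(q, T.a[f], T.b[f], T.c[f]);
              if (d2 < best) best = d2;
            }
          }
    }
    out[p] = std::sqrt(best);
  }
  return out;
}
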