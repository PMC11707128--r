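// Iso-surface extraction: marching cubes on a uniform 6-tetrahedron (Kuhn)
// decomposition of each grid cell. Table-free, watertight on fields that do
// not cross the iso-value at the grid boundary, outward-oriented triangles
// (positive side = values above the iso-value). Vertices are welded on shared
// cell edges so the output is a connected, indexed mesh in voxel-index space.
#include <Rcpp.h>
#include <unordered_map>
#include <cstdint>
using namespace Rcpp;

namespace {

const int TETS[6][4] = {
  {0, 5, 1, 6}, {0, 1, 2, 6}, {0, 2, 3, 6},
  {0, 3, 7, 6}, {0, 7, 4, 6}, {0, 4, 5, 6}};
const int CORN[8][3] = {
  {0, 0, 0}, {1, 0, 0}, {1, 1, 0}, {0, 1, 0},
  {0, 0, 1}, {1, 0, 1}, {1, 1, 1}, {0, 1, 1}};

struct MeshAcc {
  std::vector<double> vx, vy, vz;
  std::vector<int> f0, f1, f2;
  std::unordered_map<uint64_t, int> edge_map;
  uint64_t ntot;  // grid vertex count; (ga, gb) keys are exact, no collisions

  explicit MeshAcc(uint64_t n) : ntot(n) {}

  int edge_vertex(uint64_t ga, uint64_t gb, const double* pa, const double* pb,
                  double va, double vb, double iso) {
    double t = (iso - va) / (vb - va);
    if (t <= 0.0) { t = 0.0; gb = ga; }
    else if (t >= 1.0) { t = 1.0; ga = gb; pa = pb; }
    else if (ga > gb) {
      std::swap(ga, gb); const double* tp = pa; pa = pb; pb = tp;
      std::swap(va, vb); t = (iso - va) / (vb - va);
    }
    uint64_t key = ga * ntot + gb;
    auto it = edge_map.find(key);
    if (it != edge_map.end()) return it->second;
    int id = (int)vx.size();
    if (ga == gb) { vx.push_back(pa[0]); vy.push_back(pa[1]); vz.push_back(pa[2]); }
    else {
      vx.push_back(pa[0] + t * (pb[0] - pa[0]));
      vy.push_back(pa[1] + t * (pb[1] - pa[1]));
      vz.push_back(pa[2] + t * (pb[2] - pa[2]));
    }
    edge_map.emplace(key, id);
    return id;
  }

  void tri(int a, int b, int c, const double* ref_out) {
    if (a == b || b == c || a == c) return;
    // orient so the normal points toward the outside reference point
    double e1x = vx[b] - vx[a], e1y = vy[b] - vy[a], e1z = vz[b] - vz[a];
    double e2x = vx[c] - vx[a], e2y = vy[c] - vy[a], e2z = vz[c] - vz[a];
    double nxx = e1y * e2z - e1z * e2y;
    double nyy = e1z * e2x - e1x * e2z;
    double nzz = e1x * e2y - e1y * e2x;
    double cx = (vx[a] + vx[b] + vx[c]) / 3.0;
    double cy = (vy[a] + vy[b] + vy[c]) / 3.0;
    double cz = (vz[a] + vz[b] + vz[c]) / 3.0;
    double d = nxx * (ref_out[0] - cx) + nyy * (ref_out[1] - cy) + nzz * (ref_out[2] - cz);
    if (d < 0) std::swap(b, c);
    f0.push_back(a); f1.push_back(b); f2.push_back(c);
  }
};

}  // namespace

// [[Rcpp::export(name = ".cs_marching_tets")]]
List cs_marching_tets(const NumericVector& field, const IntegerVector& dims, double iso) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double* F = field.begin();
  MeshAcc acc((uint64_t)nx * ny * nz);
  double pos[8][3];
  double val[8];
  uint64_t gid[8];
  for (int k = 0; k + 1 < nz; ++k)
    for (int j = 0; j + 1 < ny; ++j)
      for (int i = 0; i + 1 < nx; ++i) {
        int n_in = 0;
        for (int c = 0; c < 8; ++c) {
          int ci = i + CORN[c][0], cj = j + CORN[c][1], ck = k + CORN[c][2];
          uint64_t g = (uint64_t)ci + (uint64_t)nx * ((uint64_t)cj + (uint64_t)ny * ck);
          gid[c] = g;
          val[c] = F[g];
          pos[c][0] = ci; pos[c][1] = cj; pos[c][2] = ck;
          if (val[c] > iso) ++n_in;
        }
        if (n_in == 0 || n_in == 8) continue;
        for (int t = 0; t < 6; ++t) {
          const int* T = TETS[t];
          bool in[4];
          int ni = 0;
          for (int c = 0; c < 4; ++c) { in[c] = val[T[c]] > iso; if (in[c]) ++ni; }
          if (ni == 0 || ni == 4) continue;
          if (ni == 1 || ni == 3) {
            int a = -1;
            for (int c = 0; c < 4; ++c) if (in[c] == (ni == 1)) { a = c; break; }
            int o[3], m = 0;
            for (int c = 0; c < 4; ++c) if (c != a) o[m++] = c;
            int va[3];
            for (int c = 0; c < 3; ++c)
              va[c] = acc.edge_vertex(gid[T[a]], gid[T[o[c]]], pos[T[a]], pos[T[o[c]]],
                                      val[T[a]], val[T[o[c]]], iso);
            // reference outside point: any vertex on the low side
            int ref = (ni == 1) ? T[o[0]] : T[a];
            acc.tri(va[0], va[1], va[2], pos[ref]);
          } else {
            int I[2], O[2], mi = 0, mo = 0;
            for (int c = 0; c < 4; ++c) { if (in[c]) I[mi++] = c; else O[mo++] = c; }
            int q0 = acc.edge_vertex(gid[T[I[0]]], gid[T[O[0]]], pos[T[I[0]]], pos[T[O[0]]], val[T[I[0]]], val[T[O[0]]], iso);
            int q1 = acc.edge_vertex(gid[T[I[0]]], gid[T[O[1]]], pos[T[I[0]]], pos[T[O[1]]], val[T[I[0]]], val[T[O[1]]], iso);
            int q2 = acc.edge_vertex(gid[T[I[1]]], gid[T[O[1]]], pos[T[I[1]]], pos[T[O[1]]], val[T[I[1]]], val[T[O[1]]], iso);
            int q3 = acc.edge_vertex(gid[T[I[1]]], gid[T[O[0]]], pos[T[I[1]]], pos[T[O[0]]], val[T[I[1]]], val[T[O[0]]], iso);
            acc.tri(q0, q1, q2, pos[T[O[0]]]);
            acc.tri(q0, q2, q3, pos[T[O[0]]]);
          }
        }
      }
  const int nv = (int)acc.vx.size(), nf = (int)acc.f0.size();
  NumericMatrix V(nv, 3);
  IntegerMatrix Fc(nf, 3);
  for (int v = 0; v < nv; ++v) { V(v, 0) = acc.vx[v]; V(v, 1) = acc.vy[v]; V(v, 2) = acc.vz[v]; }
  for (int f = 0; f < nf; ++f) { Fc(f, 0) = acc.f0[f] + 1; Fc(f, 1) = acc.f1[f] + 1; Fc(f, 2) = acc.f2[f] + 1; }
  return List::create(_["vertices"] = V, _["faces"] = Fc);
}
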