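#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <unordered_map>
#include <vector>
#include <algorithm>

using namespace Rcpp;

static inline double sq(double x) { return x * x; }

// Iso-surface extraction by marching tetrahedra on the Kuhn (6-tetrahedra)
// decomposition of each grid cell. The Kuhn split triangulates shared cell
// faces identically in neighbouring cells, so the extracted surface of any
// bounded region is watertight by construction. Vertices are welded on grid
// edges, keyed by the pair of lattice points the edge joins.
//
// Coordinates are returned in the grid frame (index * spacing, mm); the
// caller applies direction cosines and origin.

struct MTState {
  std::unordered_map<uint64_t, int> edge_vertex;
  std::vector<double> vx, vy, vz;
  std::vector<int> f0, f1, f2;
};

static inline uint64_t edge_key(uint64_t a, uint64_t b) {
  if (a > b) std::swap(a, b);
  return (a << 32) | b;
}

static int edge_point(MTState& st, uint64_t ga, uint64_t gb, const double* pa,
                      const double* pb, double fa, double fb, double level) {
  uint64_t key = edge_key(ga, gb);
  auto it = st.edge_vertex.find(key);
  if (it != st.edge_vertex.end()) return it->second;
  double t = (level - fa) / (fb - fa);
  if (t < 0) t = 0;
  if (t > 1) t = 1;
  st.vx.push_back(pa[0] + t * (pb[0] - pa[0]));
  st.vy.push_back(pa[1] + t * (pb[1] - pa[1]));
  st.vz.push_back(pa[2] + t * (pb[2] - pa[2]));
  int id = (int)st.vx.size() - 1;
  st.edge_vertex[key] = id;
  return id;
}

// Append triangle (a,b,c), flipping if needed so the normal points away from
// the inside reference point `ref` (a point on the inside of the surface).
static void add_tri(MTState& st, int a, int b, int c, const double ref[3]) {
  double ax = st.vx[a], ay = st.vy[a], az = st.vz[a];
  double ux = st.vx[b] - ax, uy = st.vy[b] - ay, uz = st.vz[b] - az;
  double wx = st.vx[c] - ax, wy = st.vy[c] - ay, wz = st.vz[c] - az;
  double nx = uy * wz - uz * wy;
  double ny = uz * wx - ux * wz;
  double nz = ux * wy - uy * wx;
  double cx = (ax + st.vx[b] + st.vx[c]) / 3.0 - ref[0];
  double cy = (ay + st.vy[b] + st.vy[c]) / 3.0 - ref[1];
  double cz = (az + st.vz[b] + st.vz[c]) / 3.0 - ref[2];
  if (nx * cx + ny * cy + nz * cz < 0) std::swap(b, c);
  st.f0.push_back(a);
  st.f1.push_back(b);
  st.f2.push_back(c);
}

// [[Rcpp::export]]
List cpp_marching_tets(NumericVector field, IntegerVector dim,
                       NumericVector spacing, double level) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const size_t sy = (size_t)nx, sz = (size_t)nx * ny;
  const double spx = spacing[0], spy = spacing[1], spz = spacing[2];

  // Kuhn tetrahedra: corner 0 and 7 plus the two intermediate corners along
  // each of the six axis orderings. Corner bit order: x = bit0, y = bit1,
  // z = bit2.
  static const int tets[6][4] = {{0, 1, 3, 7}, {0, 1, 5, 7}, {0, 2, 3, 7},
                                 {0, 2, 6, 7}, {0, 4, 5, 7}, {0, 4, 6, 7}};

  MTState st;
  int corner_off[8][3];
  for (int c = 0; c < 8; c++) {
    corner_off[c][0] = c & 1;
    corner_off[c][1] = (c >> 1) & 1;
    corner_off[c][2] = (c >> 2) & 1;
  }

  for (int k = 0; k < nz - 1; k++) {
    for (int j = 0; j < ny - 1; j++) {
      for (int i = 0; i < nx - 1; i++) {
        double fv[8];
        uint64_t gid[8];
        double pos[8][3];
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; c++) {
          int ii = i + corner_off[c][0], jj = j + corner_off[c][1],
              kk = k + corner_off[c][2];
          gid[c] = (uint64_t)kk * sz + (uint64_t)jj * sy + ii;
          fv[c] = field[gid[c]];
          pos[c][0] = ii * spx;
          pos[c][1] = jj * spy;
          pos[c][2] = kk * spz;
          if (fv[c] > level) any_in = true; else any_out = true;
        }
        if (!any_in || !any_out) continue;
        for (int t = 0; t < 6; t++) {
          int vi[4] = {tets[t][0], tets[t][1], tets[t][2], tets[t][3]};
          int in_idx[4], out_idx[4], nin = 0, nout = 0;
          for (int q = 0; q < 4; q++) {
            if (fv[vi[q]] > level) in_idx[nin++] = vi[q];
            else out_idx[nout++] = vi[q];
          }
          if (nin == 0 || nin == 4) continue;
          double ref[3] = {0, 0, 0};
          for (int q = 0; q < nin; q++) {
            ref[0] += pos[in_idx[q]][0];
            ref[1] += pos[in_idx[q]][1];
            ref[2] += pos[in_idx[q]][2];
          }
          ref[0] /= nin; ref[1] /= nin; ref[2] /= nin;
          if (nin == 1) {
            int A = in_idx[0];
            int e0 = edge_point(st, gid[A], gid[out_idx[0]], pos[A],
                                pos[out_idx[0]], fv[A], fv[out_idx[0]], level);
            int e1 = edge_point(st, gid[A], gid[out_idx[1]], pos[A],
                                pos[out_idx[1]], fv[A], fv[out_idx[1]], level);
            int e2 = edge_point(st, gid[A], gid[out_idx[2]], pos[A],
                                pos[out_idx[2]], fv[A], fv[out_idx[2]], level);
            add_tri(st, e0, e1, e2, ref);
          } else if (nin == 3) {
            int A = out_idx[0];
            int e0 = edge_point(st, gid[in_idx[0]], gid[A], pos[in_idx[0]],
                                pos[A], fv[in_idx[0]], fv[A], level);
            int e1 = edge_point(st, gid[in_idx[1]], gid[A], pos[in_idx[1]],
                                pos[A], fv[in_idx[1]], fv[A], level);
            int e2 = edge_point(st, gid[in_idx[2]], gid[A], pos[in_idx[2]],
                                pos[A], fv[in_idx[2]], fv[A], level);
            add_tri(st, e0, e1, e2, ref);
          } else {  // nin == 2: quad split into two triangles
            int A = in_idx[0], B = in_idx[1], C = out_idx[0], D = out_idx[1];
            int eAC = edge_point(st, gid[A], gid[C], pos[A], pos[C], fv[A],
                                 fv[C], level);
            int eAD = edge_point(st, gid[A], gid[D], pos[A], pos[D], fv[A],
                                 fv[D], level);
            int eBC = edge_point(st, gid[B], gid[C], pos[B], pos[C], fv[B],
                                 fv[C], level);
            int eBD = edge_point(st, gid[B], gid[D], pos[B], pos[D], fv[B],
                                 fv[D], level);
            add_tri(st, eAC, eBC, eBD, ref);
            add_tri(st, eAC, eBD, eAD, ref);
          }
        }
      }
    }
  }

  int nv = (int)st.vx.size(), nf = (int)st.f0.size();
  NumericMatrix V(nv, 3);
  for (int q = 0; q < nv; q++) {
    V(q, 0) = st.vx[q];
    V(q, 1) = st.vy[q];
    V(q, 2) = st.vz[q];
  }
  IntegerMatrix F(nf, 3);
  for (int q = 0; q < nf; q++) {
    F(q, 0) = st.f0[q] + 1;
    F(q, 1) = st.f1[q] + 1;
    F(q, 2) = st.f2[q] + 1;
  }
  return List::create(_["vertices"] = V, _["faces"] = F);
}

// Watertightness/orientation audit: every undirected edge must be used by
// exactly two faces, once in each direction. Returns counts of violations.
// [[Rcpp::export]]
List cpp_edge_audit(IntegerMatrix F, int nv) {
  std::unordered_map<uint64_t, int> fwd;
  int nf = F.nrow();
  for (int q = 0; q < nf; q++) {
    int a = F(q, 0) - 1, b = F(q, 1) - 1, c = F(q, 2) - 1;
    int e[3][2] = {{a, b}, {b, c}, {c, a}};
    for (int t = 0; t < 3; t++) {
      uint64_t key = ((uint64_t)e[t][0] << 32) | (uint64_t)e[t][1];
      fwd[key]++;
    }
  }
  int unmatched = 0, duplicated = 0;
  for (auto& kv : fwd) {
    if (kv.second != 1) duplicated++;
    uint64_t rev = (kv.first << 32) | (kv.first >> 32);
    auto it = fwd.find(rev);
    if (it == fwd.end() || it->second != kv.second) unmatched++;
  }
  return List::create(_["unmatched"] = unmatched, _["duplicated"] = duplicated,
                      _["n_edges"] = (int)fwd.size());
}

// Parity (ray casting) voxelization of a closed mesh given in the grid frame
// (mm, axes-aligned). Rays run along +x through voxel centers, jittered off
// the lattice to dodge vertex/edge hits.
// [[Rcpp::export]]
LogicalVector cpp_voxelize(NumericMatrix V, IntegerMatrix F, IntegerVector dim,
                           NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double spx = spacing[0], spy = spacing[1], spz = spacing[2];
  const double ey = 0.37e-3 * spy, ez = 0.41e-3 * spz;
  std::vector<std::vector<double>> crossings((size_t)ny * nz);
  int nf = F.nrow();
  for (int q = 0; q < nf; q++) {
    int a = F(q, 0) - 1, b = F(q, 1) - 1, c = F(q, 2) - 1;
    double x0 = V(a, 0), y0 = V(a, 1), z0 = V(a, 2);
    double x1 = V(b, 0), y1 = V(b, 1), z1 = V(b, 2);
    double x2 = V(c, 0), y2 = V(c, 1), z2 = V(c, 2);
    double denom = (y1 - y0) * (z2 - z0) - (y2 - y0) * (z1 - z0);
    if (std::fabs(denom) < 1e-14) continue;  // parallel to ray bundle
    double ylo = std::min(y0, std::min(y1, y2)),
           yhi = std::max(y0, std::max(y1, y2));
    double zlo = std::min(z0, std::min(z1, z2)),
           zhi = std::max(z0, std::max(z1, z2));
    int j0 = (int)std::ceil((ylo - ey) / spy), j1 = (int)std::floor((yhi - ey) / spy);
    int k0 = (int)std::ceil((zlo - ez) / spz), k1 = (int)std::floor((zhi - ez) / spz);
    if (j0 < 0) j0 = 0;
    if (j1 > ny - 1) j1 = ny - 1;
    if (k0 < 0) k0 = 0;
    if (k1 > nz - 1) k1 = nz - 1;
    for (int k = k0; k <= k1; k++) {
      double rz = k * spz + ez;
      for (int j = j0; j <= j1; j++) {
        double ry = j * spy + ey;
        double b1 = ((ry - y0) * (z2 - z0) - (rz - z0) * (y2 - y0)) / denom;
        double b2 = ((y1 - y0) * (rz - z0) - (z1 - z0) * (ry - y0)) / denom;
        if (b1 < 0 || b2 < 0 || b1 + b2 > 1) continue;
        crossings[(size_t)k * ny + j].push_back(x0 + b1 * (x1 - x0) +
                                                b2 * (x2 - x0));
      }
    }
  }
  LogicalVector out((size_t)nx * ny * nz, FALSE);
  const size_t sy = (size_t)nx, sz = (size_t)nx * ny;
  for (int k = 0; k < nz; k++) {
    for (int j = 0; j < ny; j++) {
      std::vector<double>& cr = crossings[(size_t)k * ny + j];
      if (cr.size() < 2) continue;
      std::sort(cr.begin(), cr.end());
      size_t npair = cr.size() / 2;
      for (size_t t = 0; t < npair; t++) {
        double xin = cr[2 * t], xout = cr[2 * t + 1];
        int i0 = (int)std::ceil(xin / spx), i1 = (int)std::floor(xout / spx);
        if (i0 < 0) i0 = 0;
        if (i1 > nx - 1) i1 = nx - 1;
        for (int i = i0; i <= i1; i++)
          out[(size_t)k * sz + (size_t)j * sy + i] = TRUE;
      }
    }
  }
  return out;
}

// Exact closest-point distance from query points to a triangle soup, using a
// uniform spatial hash over triangle bounding boxes. Queries and vertices
// share a frame (grid-frame mm). Queries with no triangle within
// `max_dist` report Inf.
static inline double dot3(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}

// Ericson, Real-Time Collision Detection: closest point on triangle (a,b,c)
// to p; returns squared distance.
static double tri_dist2(const double* p, const double* a, const double* b,
                        const double* c) {
  double ab[3], ac[3], ap[3];
  for (int i = 0; i < 3; i++) {
    ab[i] = b[i] - a[i];
    ac[i] = c[i] - a[i];
    ap[i] = p[i] - a[i];
  }
  double d1 = dot3(ab, ap), d2 = dot3(ac, ap);
  if (d1 <= 0 && d2 <= 0) return dot3(ap, ap);
  double bp[3];
  for (int i = 0; i < 3; i++) bp[i] = p[i] - b[i];
  double d3 = dot3(ab, bp), d4 = dot3(ac, bp);
  if (d3 >= 0 && d4 <= d3) return dot3(bp, bp);
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    double v = d1 / (d1 - d3), e[3];
    for (int i = 0; i < 3; i++) e[i] = ap[i] - v * ab[i];
    return dot3(e, e);
  }
  double cp[3];
  for (int i = 0; i < 3; i++) cp[i] = p[i] - c[i];
  double d5 = dot3(ab, cp), d6 = dot3(ac, cp);
  if (d6 >= 0 && d5 <= d6) return dot3(cp, cp);
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    double w = d2 / (d2 - d6), e[3];
    for (int i = 0; i < 3; i++) e[i] = ap[i] - w * ac[i];
    return dot3(e, e);
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6)), e[3];
    // closest point is b + w*(c-b)
    for (int i = 0; i < 3; i++) e[i] = p[i] - (b[i] + w * (c[i] - b[i]));
    return dot3(e, e);
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom, e[3];
  for (int i = 0; i < 3; i++) e[i] = ap[i] - (ab[i] * v + ac[i] * w);
  return dot3(e, e);
}

// [[Rcpp::export]]
NumericVector cpp_mesh_distance(NumericMatrix V, IntegerMatrix F,
                                NumericMatrix Q, double cell,
                                double max_dist) {
  const int nf = F.nrow(), nq = Q.nrow();
  // mesh bbox
  double lo[3], hi[3];
  for (int m = 0; m < 3; m++) {
    lo[m] = R_PosInf;
    hi[m] = R_NegInf;
  }
  for (int i = 0; i < V.nrow(); i++) {
    for (int m = 0; m < 3; m++) {
      if (V(i, m) < lo[m]) lo[m] = V(i, m);
      if (V(i, m) > hi[m]) hi[m] = V(i, m);
    }
  }
  int gd[3];
  for (int m = 0; m < 3; m++) {
    gd[m] = std::max(1, (int)std::floor((hi[m] - lo[m]) / cell) + 1);
  }
  size_t ncell = (size_t)gd[0] * gd[1] * gd[2];
  // count-then-fill CSR binning of triangles by bbox overlap
  std::vector<int> counts(ncell + 1, 0);
  std::vector<int> c0(nf), c1(nf), r0(nf), r1(nf), s0(nf), s1(nf);
  for (int q = 0; q < nf; q++) {
    double tlo[3], thi[3];
    for (int m = 0; m < 3; m++) {
      double va = V(F(q, 0) - 1, m), vb = V(F(q, 1) - 1, m),
             vcc = V(F(q, 2) - 1, m);
      tlo[m] = std::min(va, std::min(vb, vcc));
      thi[m] = std::max(va, std::max(vb, vcc));
    }
    c0[q] = std::max(0, (int)((tlo[0] - lo[0]) / cell));
    c1[q] = std::min(gd[0] - 1, (int)((thi[0] - lo[0]) / cell));
    r0[q] = std::max(0, (int)((tlo[1] - lo[1]) / cell));
    r1[q] = std::min(gd[1] - 1, (int)((thi[1] - lo[1]) / cell));
    s0[q] = std::max(0, (int)((tlo[2] - lo[2]) / cell));
    s1[q] = std::min(gd[2] - 1, (int)((thi[2] - lo[2]) / cell));
    for (int k = s0[q]; k <= s1[q]; k++)
      for (int j = r0[q]; j <= r1[q]; j++)
        for (int i = c0[q]; i <= c1[q]; i++)
          counts[(size_t)k * gd[0] * gd[1] + (size_t)j * gd[0] + i + 1]++;
  }
  for (size_t t = 1; t <= ncell; t++) counts[t] += counts[t - 1];
  std::vector<int> items(counts[ncell]);
  std::vector<int> cursor(counts.begin(), counts.end() - 1);
  for (int q = 0; q < nf; q++) {
    for (int k = s0[q]; k <= s1[q]; k++)
      for (int j = r0[q]; j <= r1[q]; j++)
        for (int i = c0[q]; i <= c1[q]; i++) {
          size_t cidx = (size_t)k * gd[0] * gd[1] + (size_t)j * gd[0] + i;
          items[cursor[cidx]++] = q;
        }
  }

  std::vector<int> stamp(nf, -1);
  NumericVector out(nq);
  const int max_ring = (int)std::ceil(max_dist / cell) + 2;
  for (int qi = 0; qi < nq; qi++) {
    double p[3] = {Q(qi, 0), Q(qi, 1), Q(qi, 2)};
    int ci[3];
    for (int m = 0; m < 3; m++) {
      ci[m] = (int)std::floor((p[m] - lo[m]) / cell);
    }
    double best2 = R_PosInf;
    for (int ring = 0; ring <= max_ring; ring++) {
      // cells at Chebyshev distance `ring` are at least (ring-1)*cell away
      if (best2 <= sq((ring - 1) * cell)) break;
      bool any_cell = false;
      for (int dk = -ring; dk <= ring; dk++) {
        int k = ci[2] + dk;
        if (k < 0 || k >= gd[2]) continue;
        for (int dj = -ring; dj <= ring; dj++) {
          int j = ci[1] + dj;
          if (j < 0 || j >= gd[1]) continue;
          bool face_jk = std::abs(dk) == ring || std::abs(dj) == ring;
          for (int di = -ring; di <= ring; di++) {
            if (!face_jk && std::abs(di) != ring) continue;  // shell only
            int i = ci[0] + di;
            if (i < 0 || i >= gd[0]) continue;
            any_cell = true;
            size_t cidx = (size_t)k * gd[0] * gd[1] + (size_t)j * gd[0] + i;
            for (int t = counts[cidx]; t < counts[cidx + 1]; t++) {
              int f = items[t];
              if (stamp[f] == qi) continue;
              stamp[f] = qi;
              double a[3], b[3], c[3];
              for (int m = 0; m < 3; m++) {
                a[m] = V(F(f, 0) - 1, m);
                b[m] = V(F(f, 1) - 1, m);
                c[m] = V(F(f, 2) - 1, m);
              }
              double d2v = tri_dist2(p, a, b, c);
              if (d2v < best2) best2 = d2v;
            }
          }
        }
      }
      if (!any_cell && ring > 0 && best2 < R_PosInf) break;
    }
    out[qi] = std::isfinite(best2) ? std::sqrt(best2) : R_PosInf;
  }
  return out;
}
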