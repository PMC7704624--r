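#include <Rcpp.h>
#include <unordered_map>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Nearest neighbours (brute force; meshes are a few thousand to a few ten
// thousand points, so O(N*M) with tight inner loops is fast enough and
// avoids a tree dependency).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_nn(NumericMatrix query, NumericMatrix ref) {
  const int nq = query.nrow(), nr = ref.nrow();
  IntegerVector idx(nq);
  NumericVector dist(nq);
  for (int i = 0; i < nq; ++i) {
    const double qx = query(i, 0), qy = query(i, 1), qz = query(i, 2);
    double best = R_PosInf; int bj = 0;
    for (int j = 0; j < nr; ++j) {
      const double dx = ref(j, 0) - qx, dy = ref(j, 1) - qy, dz = ref(j, 2) - qz;
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) { best = d2; bj = j; }
    }
    idx[i] = bj + 1;
    dist[i] = std::sqrt(best);
  }
  return List::create(_["index"] = idx, _["dist"] = dist);
}

// [[Rcpp::export]]
double cpp_nn_sumdist(NumericMatrix query, NumericMatrix ref) {
  const int nq = query.nrow(), nr = ref.nrow();
  // uniform grid over the reference points
  double lo[3] = {R_PosInf, R_PosInf, R_PosInf};
  double hi[3] = {R_NegInf, R_NegInf, R_NegInf};
  for (int j = 0; j < nr; ++j)
    for (int d = 0; d < 3; ++d) {
      if (ref(j, d) < lo[d]) lo[d] = ref(j, d);
      if (ref(j, d) > hi[d]) hi[d] = ref(j, d);
    }
  const double span = std::max(std::max(hi[0] - lo[0], hi[1] - lo[1]),
                               hi[2] - lo[2]);
  const double cell = std::max(span / std::max(4.0, std::cbrt((double)nr)),
                               1e-6);
  const int nx = (int)((hi[0] - lo[0]) / cell) + 1;
  const int ny = (int)((hi[1] - lo[1]) / cell) + 1;
  const int nz = (int)((hi[2] - lo[2]) / cell) + 1;
  auto bin = [&](int i, int j, int k) -> int64_t {
    return (int64_t)i + (int64_t)nx * ((int64_t)j + (int64_t)ny * (int64_t)k);
  };
  auto clampi = [](int i, int n) { return i < 0 ? 0 : (i >= n ? n - 1 : i); };
  std::vector<std::vector<int>> bins((size_t)nx * ny * nz);
  for (int j = 0; j < nr; ++j) {
    const int i = clampi((int)((ref(j, 0) - lo[0]) / cell), nx);
    const int jj = clampi((int)((ref(j, 1) - lo[1]) / cell), ny);
    const int k = clampi((int)((ref(j, 2) - lo[2]) / cell), nz);
    bins[bin(i, jj, k)].push_back(j);
  }
  const int rmax = std::max(std::max(nx, ny), nz);
  double total = 0.0;
  for (int i = 0; i < nq; ++i) {
    const double qx = query(i, 0), qy = query(i, 1), qz = query(i, 2);
    const int qi = clampi((int)((qx - lo[0]) / cell), nx);
    const int qj = clampi((int)((qy - lo[1]) / cell), ny);
    const int qk = clampi((int)((qz - lo[2]) / cell), nz);
    double best = R_PosInf;
    for (int r = 0; r <= rmax; ++r) {
      if ((r - 1) * cell > best) break;
      const int i0 = qi - r, i1 = qi + r;
      const int j0 = qj - r, j1 = qj + r;
      const int k0 = qk - r, k1 = qk + r;
      for (int kk = k0; kk <= k1; ++kk) {
        if (kk < 0 || kk >= nz) continue;
        for (int jj = j0; jj <= j1; ++jj) {
          if (jj < 0 || jj >= ny) continue;
          for (int ii = i0; ii <= i1; ++ii) {
            if (ii < 0 || ii >= nx) continue;
            if (r > 0 && ii != i0 && ii != i1 && jj != j0 && jj != j1 &&
                kk != k0 && kk != k1)
              continue;
            for (int t : bins[bin(ii, jj, kk)]) {
              const double dx = ref(t, 0) - qx, dy = ref(t, 1) - qy,
                           dz = ref(t, 2) - qz;
              const double d = std::sqrt(dx * dx + dy * dy + dz * dz);
              if (d < best) best = d;
            }
          }
        }
      }
    }
    total += best;
  }
  return total;
}

// [[Rcpp::export]]
IntegerVector cpp_max_pair(NumericMatrix v) {
  const int n = v.nrow();
  double best = -1.0; int bi = 0, bj = 0;
  for (int i = 0; i < n; ++i) {
    const double xi = v(i, 0), yi = v(i, 1), zi = v(i, 2);
    for (int j = i + 1; j < n; ++j) {
      const double dx = v(j, 0) - xi, dy = v(j, 1) - yi, dz = v(j, 2) - zi;
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 > best) { best = d2; bi = i; bj = j; }
    }
  }
  return IntegerVector::create(bi + 1, bj + 1);
}

// ---------------------------------------------------------------------------
// Closest point on a triangle mesh (Ericson's region classification), with
// per-face bounding-sphere pruning seeded by the nearest-vertex distance.
// ---------------------------------------------------------------------------

static inline void closest_on_tri(const double p[3], const double a[3],
                                  const double b[3], const double c[3],
                                  double out[3]) {
  double ab[3], ac[3], ap[3];
  for (int k = 0; k < 3; ++k) {
    ab[k] = b[k] - a[k]; ac[k] = c[k] - a[k]; ap[k] = p[k] - a[k];
  }
  const double d1 = ab[0] * ap[0] + ab[1] * ap[1] + ab[2] * ap[2];
  const double d2 = ac[0] * ap[0] + ac[1] * ap[1] + ac[2] * ap[2];
  if (d1 <= 0.0 && d2 <= 0.0) { for (int k = 0; k < 3; ++k) out[k] = a[k]; return; }
  double bp[3];
  for (int k = 0; k < 3; ++k) bp[k] = p[k] - b[k];
  const double d3 = ab[0] * bp[0] + ab[1] * bp[1] + ab[2] * bp[2];
  const double d4 = ac[0] * bp[0] + ac[1] * bp[1] + ac[2] * bp[2];
  if (d3 >= 0.0 && d4 <= d3) { for (int k = 0; k < 3; ++k) out[k] = b[k]; return; }
  const double vc = d1 * d4 - d3 * d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    const double v = d1 / (d1 - d3);
    for (int k = 0; k < 3; ++k) out[k] = a[k] + v * ab[k];
    return;
  }
  double cp[3];
  for (int k = 0; k < 3; ++k) cp[k] = p[k] - c[k];
  const double d5 = ab[0] * cp[0] + ab[1] * cp[1] + ab[2] * cp[2];
  const double d6 = ac[0] * cp[0] + ac[1] * cp[1] + ac[2] * cp[2];
  if (d6 >= 0.0 && d5 <= d6) { for (int k = 0; k < 3; ++k) out[k] = c[k]; return; }
  const double vb = d5 * d2 - d1 * d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    const double w = d2 / (d2 - d6);
    for (int k = 0; k < 3; ++k) out[k] = a[k] + w * ac[k];
    return;
  }
  const double va = d3 * d6 - d5 * d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    const double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    for (int k = 0; k < 3; ++k) out[k] = b[k] + w * (c[k] - b[k]);
    return;
  }
  const double denom = 1.0 / (va + vb + vc);
  const double v = vb * denom, w = vc * denom;
  for (int k = 0; k < 3; ++k) out[k] = a[k] + ab[k] * v + ac[k] * w;
}

// Uniform grid over face centroids for closest-point pruning.  Cells are
// sized from the largest face bounding radius, so a shell search with a
// conservative lower bound terminates after a few rings on uniform meshes.
namespace {

struct FaceGrid {
  double ox, oy, oz, cell, max_rad;
  int nx, ny, nz;
  std::vector<std::vector<int>> bins;
  int clampi(int i, int n) const { return i < 0 ? 0 : (i >= n ? n - 1 : i); }
  int64_t bin(int i, int j, int k) const {
    return (int64_t)i + (int64_t)nx * ((int64_t)j + (int64_t)ny * (int64_t)k);
  }
};

void build_face_grid(FaceGrid &g, const NumericMatrix &v,
                     const IntegerMatrix &f, std::vector<double> &cx,
                     std::vector<double> &cy, std::vector<double> &cz,
                     std::vector<double> &rad) {
  const int nf = f.nrow();
  cx.resize(nf); cy.resize(nf); cz.resize(nf); rad.resize(nf);
  double lo[3] = {R_PosInf, R_PosInf, R_PosInf};
  double hi[3] = {R_NegInf, R_NegInf, R_NegInf};
  double max_rad = 0.0;
  for (int t = 0; t < nf; ++t) {
    const int a = f(t, 0) - 1, b = f(t, 1) - 1, c = f(t, 2) - 1;
    const double mx = (v(a, 0) + v(b, 0) + v(c, 0)) / 3.0;
    const double my = (v(a, 1) + v(b, 1) + v(c, 1)) / 3.0;
    const double mz = (v(a, 2) + v(b, 2) + v(c, 2)) / 3.0;
    cx[t] = mx; cy[t] = my; cz[t] = mz;
    double r2 = 0.0;
    const int ids[3] = {a, b, c};
    for (int s = 0; s < 3; ++s) {
      const double dx = v(ids[s], 0) - mx, dy = v(ids[s], 1) - my,
                   dz = v(ids[s], 2) - mz;
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 > r2) r2 = d2;
    }
    rad[t] = std::sqrt(r2);
    if (rad[t] > max_rad) max_rad = rad[t];
    if (mx < lo[0]) lo[0] = mx; if (mx > hi[0]) hi[0] = mx;
    if (my < lo[1]) lo[1] = my; if (my > hi[1]) hi[1] = my;
    if (mz < lo[2]) lo[2] = mz; if (mz > hi[2]) hi[2] = mz;
  }
  g.max_rad = max_rad;
  g.cell = std::max(2.0 * max_rad, 1e-6);
  g.ox = lo[0]; g.oy = lo[1]; g.oz = lo[2];
  g.nx = std::max(1, (int)((hi[0] - lo[0]) / g.cell) + 1);
  g.ny = std::max(1, (int)((hi[1] - lo[1]) / g.cell) + 1);
  g.nz = std::max(1, (int)((hi[2] - lo[2]) / g.cell) + 1);
  g.bins.assign((size_t)g.nx * g.ny * g.nz, {});
  for (int t = 0; t < nf; ++t) {
    const int i = g.clampi((int)((cx[t] - g.ox) / g.cell), g.nx);
    const int j = g.clampi((int)((cy[t] - g.oy) / g.cell), g.ny);
    const int k = g.clampi((int)((cz[t] - g.oz) / g.cell), g.nz);
    g.bins[g.bin(i, j, k)].push_back(t);
  }
}

}  // namespace

// [[Rcpp::export]]
List cpp_closest_on_mesh(NumericMatrix p, NumericMatrix v, IntegerMatrix f) {
  const int np = p.nrow();
  FaceGrid g;
  std::vector<double> cx, cy, cz, rad;
  build_face_grid(g, v, f, cx, cy, cz, rad);
  NumericMatrix out(np, 3);
  NumericVector dist(np);
  IntegerVector face(np);
  const int rmax = std::max(std::max(g.nx, g.ny), g.nz);
  for (int i = 0; i < np; ++i) {
    const double q[3] = {p(i, 0), p(i, 1), p(i, 2)};
    const int qi = g.clampi((int)((q[0] - g.ox) / g.cell), g.nx);
    const int qj = g.clampi((int)((q[1] - g.oy) / g.cell), g.ny);
    const int qk = g.clampi((int)((q[2] - g.oz) / g.cell), g.nz);
    double best = R_PosInf;
    double bp[3] = {0, 0, 0};
    int bf = 0;
    for (int r = 0; r <= rmax; ++r) {
      // conservative lower bound for faces binned in ring r
      const double lower = (r - 1) * g.cell - g.max_rad;
      if (lower > best) break;
      const int i0 = qi - r, i1 = qi + r;
      const int j0 = qj - r, j1 = qj + r;
      const int k0 = qk - r, k1 = qk + r;
      for (int kk = k0; kk <= k1; ++kk) {
        if (kk < 0 || kk >= g.nz) continue;
        for (int jj = j0; jj <= j1; ++jj) {
          if (jj < 0 || jj >= g.ny) continue;
          for (int ii = i0; ii <= i1; ++ii) {
            if (ii < 0 || ii >= g.nx) continue;
            // only the shell of the cube (interior seen at smaller r)
            if (r > 0 && ii != i0 && ii != i1 && jj != j0 && jj != j1 &&
                kk != k0 && kk != k1)
              continue;
            const std::vector<int> &bin = g.bins[g.bin(ii, jj, kk)];
            for (int t : bin) {
              const double dx = cx[t] - q[0], dy = cy[t] - q[1],
                           dz = cz[t] - q[2];
              const double lo2 =
                std::sqrt(dx * dx + dy * dy + dz * dz) - rad[t];
              if (lo2 >= best) continue;
              const int a = f(t, 0) - 1, b = f(t, 1) - 1, c = f(t, 2) - 1;
              const double pa[3] = {v(a, 0), v(a, 1), v(a, 2)};
              const double pb[3] = {v(b, 0), v(b, 1), v(b, 2)};
              const double pc[3] = {v(c, 0), v(c, 1), v(c, 2)};
              double cp[3];
              closest_on_tri(q, pa, pb, pc, cp);
              const double ddx = cp[0] - q[0], ddy = cp[1] - q[1],
                           ddz = cp[2] - q[2];
              const double d = std::sqrt(ddx * ddx + ddy * ddy + ddz * ddz);
              if (d < best) {
                best = d; bf = t + 1;
                bp[0] = cp[0]; bp[1] = cp[1]; bp[2] = cp[2];
              }
            }
          }
        }
      }
    }
    out(i, 0) = bp[0]; out(i, 1) = bp[1]; out(i, 2) = bp[2];
    dist[i] = best; face[i] = bf;
  }
  return List::create(_["point"] = out, _["dist"] = dist, _["face"] = face);
}

// [[Rcpp::export]]
List cpp_closest_on_mesh_brute(NumericMatrix p, NumericMatrix v,
                               IntegerMatrix f) {
  const int np = p.nrow(), nv = v.nrow(), nf = f.nrow();
  // face centroids + bounding radii for pruning
  std::vector<double> cx(nf), cy(nf), cz(nf), rad(nf);
  for (int t = 0; t < nf; ++t) {
    const int a = f(t, 0) - 1, b = f(t, 1) - 1, c = f(t, 2) - 1;
    const double mx = (v(a, 0) + v(b, 0) + v(c, 0)) / 3.0;
    const double my = (v(a, 1) + v(b, 1) + v(c, 1)) / 3.0;
    const double mz = (v(a, 2) + v(b, 2) + v(c, 2)) / 3.0;
    cx[t] = mx; cy[t] = my; cz[t] = mz;
    double r2 = 0.0;
    const int ids[3] = {a, b, c};
    for (int s = 0; s < 3; ++s) {
      const double dx = v(ids[s], 0) - mx, dy = v(ids[s], 1) - my, dz = v(ids[s], 2) - mz;
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 > r2) r2 = d2;
    }
    rad[t] = std::sqrt(r2);
  }
  NumericMatrix out(np, 3);
  NumericVector dist(np);
  IntegerVector face(np);
  for (int i = 0; i < np; ++i) {
    const double q[3] = {p(i, 0), p(i, 1), p(i, 2)};
    double best = R_PosInf;
    // seed with nearest vertex
    double bp[3] = {0, 0, 0}; int bf = 0;
    for (int j = 0; j < nv; ++j) {
      const double dx = v(j, 0) - q[0], dy = v(j, 1) - q[1], dz = v(j, 2) - q[2];
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) { best = d2; bp[0] = v(j, 0); bp[1] = v(j, 1); bp[2] = v(j, 2); }
    }
    best = std::sqrt(best);
    for (int t = 0; t < nf; ++t) {
      const double dx = cx[t] - q[0], dy = cy[t] - q[1], dz = cz[t] - q[2];
      const double lo = std::sqrt(dx * dx + dy * dy + dz * dz) - rad[t];
      if (lo >= best) continue;
      const int a = f(t, 0) - 1, b = f(t, 1) - 1, c = f(t, 2) - 1;
      const double pa[3] = {v(a, 0), v(a, 1), v(a, 2)};
      const double pb[3] = {v(b, 0), v(b, 1), v(b, 2)};
      const double pc[3] = {v(c, 0), v(c, 1), v(c, 2)};
      double cp[3];
      closest_on_tri(q, pa, pb, pc, cp);
      const double ddx = cp[0] - q[0], ddy = cp[1] - q[1], ddz = cp[2] - q[2];
      const double d = std::sqrt(ddx * ddx + ddy * ddy + ddz * ddz);
      if (d < best) {
        best = d; bf = t + 1;
        bp[0] = cp[0]; bp[1] = cp[1]; bp[2] = cp[2];
      }
    }
    out(i, 0) = bp[0]; out(i, 1) = bp[1]; out(i, 2) = bp[2];
    dist[i] = best; face[i] = bf;
  }
  return List::create(_["point"] = out, _["dist"] = dist, _["face"] = face);
}

// ---------------------------------------------------------------------------
// Plane / mesh cross-section: intersection segments chained into polylines.
// Vertices exactly on the plane are classified as positive so every crossed
// face yields exactly two edge intersections; the parameter t on a shared
// edge is identical for both incident faces, which makes chaining exact.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_plane_cut(NumericMatrix v, IntegerMatrix f, NumericVector p0,
                   NumericVector nrm) {
  const int nv = v.nrow(), nf = f.nrow();
  std::vector<double> s(nv);
  for (int i = 0; i < nv; ++i)
    s[i] = (v(i, 0) - p0[0]) * nrm[0] + (v(i, 1) - p0[1]) * nrm[1] +
           (v(i, 2) - p0[2]) * nrm[2];
  std::unordered_map<int64_t, int> edge_pt;  // edge key -> point id
  std::vector<double> px, py, pz;
  std::vector<int> seg_a, seg_b;
  auto edge_point = [&](int a, int b) -> int {
    if (a > b) std::swap(a, b);
    const int64_t key = (int64_t)a * (int64_t)nv + (int64_t)b;
    auto it = edge_pt.find(key);
    if (it != edge_pt.end()) return it->second;
    const double t = s[a] / (s[a] - s[b]);
    px.push_back(v(a, 0) + t * (v(b, 0) - v(a, 0)));
    py.push_back(v(a, 1) + t * (v(b, 1) - v(a, 1)));
    pz.push_back(v(a, 2) + t * (v(b, 2) - v(a, 2)));
    const int id = (int)px.size() - 1;
    edge_pt[key] = id;
    return id;
  };
  for (int t = 0; t < nf; ++t) {
    const int a = f(t, 0) - 1, b = f(t, 1) - 1, c = f(t, 2) - 1;
    const bool pa = s[a] >= 0.0, pb = s[b] >= 0.0, pc = s[c] >= 0.0;
    if (pa == pb && pb == pc) continue;
    int e1 = -1, e2 = -1;
    if (pa != pb) e1 = edge_point(a, b);
    if (pb != pc) { if (e1 < 0) e1 = edge_point(b, c); else e2 = edge_point(b, c); }
    if (pc != pa) { if (e1 < 0) e1 = edge_point(c, a); else e2 = edge_point(c, a); }
    if (e1 >= 0 && e2 >= 0 && e1 != e2) { seg_a.push_back(e1); seg_b.push_back(e2); }
  }
  const int npts = (int)px.size(), nseg = (int)seg_a.size();
  if (nseg == 0) return List::create();
  // adjacency: each point appears in at most 2 segments on a manifold mesh
  std::vector<int> adj(2 * npts, -1);  // neighbouring point ids
  std::vector<int> deg(npts, 0);
  for (int i = 0; i < nseg; ++i) {
    const int a = seg_a[i], b = seg_b[i];
    if (deg[a] < 2) adj[2 * a + deg[a]] = b;
    ++deg[a];
    if (deg[b] < 2) adj[2 * b + deg[b]] = a;
    ++deg[b];
  }
  std::vector<bool> used(npts, false);
  List comps;
  // open chains first (endpoints with degree 1), then closed loops
  for (int pass = 0; pass < 2; ++pass) {
    for (int start = 0; start < npts; ++start) {
      if (used[start]) continue;
      if (pass == 0 && deg[start] != 1) continue;
      if (pass == 1 && deg[start] < 2) continue;
      std::vector<int> chain;
      int cur = start, prev = -1;
      while (cur >= 0 && !used[cur]) {
        used[cur] = true;
        chain.push_back(cur);
        const int n1 = adj[2 * cur], n2 = adj[2 * cur + 1];
        int nxt = -1;
        if (n1 >= 0 && n1 != prev && !used[n1]) nxt = n1;
        else if (n2 >= 0 && n2 != prev && !used[n2]) nxt = n2;
        prev = cur; cur = nxt;
      }
      const bool closed = pass == 1;
      const int m = (int)chain.size();
      if (m < 2) continue;
      NumericMatrix pts(m, 3);
      for (int i = 0; i < m; ++i) {
        pts(i, 0) = px[chain[i]]; pts(i, 1) = py[chain[i]]; pts(i, 2) = pz[chain[i]];
      }
      comps.push_back(List::create(_["points"] = pts, _["closed"] = closed));
    }
  }
  return comps;
}

// ---------------------------------------------------------------------------
// Line / mesh intersection (Moller-Trumbore), all hits.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_line_mesh(NumericVector orig, NumericVector dir, NumericMatrix v,
                   IntegerMatrix f) {
  const int nf = f.nrow();
  std::vector<double> ts;
  std::vector<int> faces;
  for (int t = 0; t < nf; ++t) {
    const int ia = f(t, 0) - 1, ib = f(t, 1) - 1, ic = f(t, 2) - 1;
    double e1[3], e2[3], pv[3], tv[3], qv[3];
    for (int k = 0; k < 3; ++k) {
      e1[k] = v(ib, k) - v(ia, k);
      e2[k] = v(ic, k) - v(ia, k);
    }
    pv[0] = dir[1] * e2[2] - dir[2] * e2[1];
    pv[1] = dir[2] * e2[0] - dir[0] * e2[2];
    pv[2] = dir[0] * e2[1] - dir[1] * e2[0];
    const double det = e1[0] * pv[0] + e1[1] * pv[1] + e1[2] * pv[2];
    if (std::fabs(det) < 1e-12) continue;
    const double inv = 1.0 / det;
    for (int k = 0; k < 3; ++k) tv[k] = orig[k] - v(ia, k);
    const double u = (tv[0] * pv[0] + tv[1] * pv[1] + tv[2] * pv[2]) * inv;
    if (u < -1e-9 || u > 1.0 + 1e-9) continue;
    qv[0] = tv[1] * e1[2] - tv[2] * e1[1];
    qv[1] = tv[2] * e1[0] - tv[0] * e1[2];
    qv[2] = tv[0] * e1[1] - tv[1] * e1[0];
    const double w = (dir[0] * qv[0] + dir[1] * qv[1] + dir[2] * qv[2]) * inv;
    if (w < -1e-9 || u + w > 1.0 + 1e-9) continue;
    const double tt = (e2[0] * qv[0] + e2[1] * qv[1] + e2[2] * qv[2]) * inv;
    ts.push_back(tt);
    faces.push_back(t + 1);
  }
  return List::create(_["t"] = wrap(ts), _["face"] = wrap(faces));
}

// ---------------------------------------------------------------------------
// Naive surface nets isosurface extraction on a regular grid.
// The grid holds scalar field values (negative = inside).  One vertex is
// placed per sign-crossing cell (at the mean of its edge crossings) and one
// quad per sign-crossing grid edge, connecting the four cells around it.
// For a closed level set resolved by the grid (and strictly positive on the
// grid boundary) the output is a closed, outward-oriented triangle mesh
// with no sliver faces.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_surface_nets(NumericVector vals, IntegerVector dims,
                      NumericVector origin, double h) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  auto gid = [&](int i, int j, int k) -> int64_t {
    return (int64_t)i + (int64_t)nx * ((int64_t)j + (int64_t)ny * (int64_t)k);
  };
  const int cx = nx - 1, cy = ny - 1, cz = nz - 1;
  auto cid = [&](int i, int j, int k) -> int64_t {
    return (int64_t)i + (int64_t)cx * ((int64_t)j + (int64_t)cy * (int64_t)k);
  };
  std::unordered_map<int64_t, int> cell_vert;
  std::vector<double> vx, vy, vz;
  // cell edges: 12 edges as corner index pairs of the (i,j,k)+offsets cube
  static const int corner[8][3] = {
    {0, 0, 0}, {1, 0, 0}, {1, 1, 0}, {0, 1, 0},
    {0, 0, 1}, {1, 0, 1}, {1, 1, 1}, {0, 1, 1}};
  static const int cedge[12][2] = {
    {0, 1}, {1, 2}, {2, 3}, {3, 0}, {4, 5}, {5, 6},
    {6, 7}, {7, 4}, {0, 4}, {1, 5}, {2, 6}, {3, 7}};
  auto cell_vertex = [&](int i, int j, int k) -> int {
    const int64_t key = cid(i, j, k);
    auto it = cell_vert.find(key);
    if (it != cell_vert.end()) return it->second;
    double f[8];
    for (int c = 0; c < 8; ++c)
      f[c] = vals[gid(i + corner[c][0], j + corner[c][1], k + corner[c][2])];
    double sx = 0, sy = 0, sz = 0;
    int n = 0;
    for (int e = 0; e < 12; ++e) {
      const double fa = f[cedge[e][0]], fb = f[cedge[e][1]];
      if ((fa < 0) == (fb < 0)) continue;
      const double t = fa / (fa - fb);
      const int *pa = corner[cedge[e][0]], *pb = corner[cedge[e][1]];
      sx += pa[0] + t * (pb[0] - pa[0]);
      sy += pa[1] + t * (pb[1] - pa[1]);
      sz += pa[2] + t * (pb[2] - pa[2]);
      ++n;
    }
    if (n == 0) return -1;  // cannot happen for cells adjacent to a crossing edge
    vx.push_back(origin[0] + h * (i + sx / n));
    vy.push_back(origin[1] + h * (j + sy / n));
    vz.push_back(origin[2] + h * (k + sz / n));
    const int id = (int)vx.size() - 1;
    cell_vert[key] = id;
    return id;
  };
  std::vector<int> fa, fb, fc;
  auto quad = [&](int c0, int c1, int c2, int c3, bool flip) {
    if (c0 < 0 || c1 < 0 || c2 < 0 || c3 < 0) return;
    if (flip) { std::swap(c1, c3); }
    fa.push_back(c0 + 1); fb.push_back(c1 + 1); fc.push_back(c2 + 1);
    fa.push_back(c0 + 1); fb.push_back(c2 + 1); fc.push_back(c3 + 1);
  };
  // x-direction edges
  for (int k = 1; k < nz - 1; ++k)
    for (int j = 1; j < ny - 1; ++j)
      for (int i = 0; i < nx - 1; ++i) {
        const double f0 = vals[gid(i, j, k)], f1 = vals[gid(i + 1, j, k)];
        if ((f0 < 0) == (f1 < 0)) continue;
        // ring of cells around the edge, CCW seen from +x
        const int c0 = cell_vertex(i, j - 1, k - 1);
        const int c1 = cell_vertex(i, j, k - 1);
        const int c2 = cell_vertex(i, j, k);
        const int c3 = cell_vertex(i, j - 1, k);
        quad(c0, c1, c2, c3, !(f0 < 0));
      }
  // y-direction edges (ring CCW seen from +y: (z,x) order)
  for (int k = 1; k < nz - 1; ++k)
    for (int j = 0; j < ny - 1; ++j)
      for (int i = 1; i < nx - 1; ++i) {
        const double f0 = vals[gid(i, j, k)], f1 = vals[gid(i, j + 1, k)];
        if ((f0 < 0) == (f1 < 0)) continue;
        const int c0 = cell_vertex(i - 1, j, k - 1);
        const int c1 = cell_vertex(i - 1, j, k);
        const int c2 = cell_vertex(i, j, k);
        const int c3 = cell_vertex(i, j, k - 1);
        quad(c0, c1, c2, c3, !(f0 < 0));
      }
  // z-direction edges (ring CCW seen from +z: (x,y) order)
  for (int k = 0; k < nz - 1; ++k)
    for (int j = 1; j < ny - 1; ++j)
      for (int i = 1; i < nx - 1; ++i) {
        const double f0 = vals[gid(i, j, k)], f1 = vals[gid(i, j, k + 1)];
        if ((f0 < 0) == (f1 < 0)) continue;
        const int c0 = cell_vertex(i - 1, j - 1, k);
        const int c1 = cell_vertex(i, j - 1, k);
        const int c2 = cell_vertex(i, j, k);
        const int c3 = cell_vertex(i - 1, j, k);
        quad(c0, c1, c2, c3, !(f0 < 0));
      }
  const int nvv = (int)vx.size(), nff = (int)fa.size();
  NumericMatrix V(nvv, 3);
  for (int i = 0; i < nvv; ++i) { V(i, 0) = vx[i]; V(i, 1) = vy[i]; V(i, 2) = vz[i]; }
  IntegerMatrix F(nff, 3);
  for (int i = 0; i < nff; ++i) { F(i, 0) = fa[i]; F(i, 1) = fb[i]; F(i, 2) = fc[i]; }
  return List::create(_["vertices"] = V, _["faces"] = F);
}
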