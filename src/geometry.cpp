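// Geometry kernels: closest point on a triangle mesh, triangle-triangle
// intersection tests, voxel-grid tagging and harmonic Laplace solves for
// cage binding, trilinear field sampling, and parity voxelization.
// All indices crossing the R boundary are 0-based unless noted; R wrappers
// convert.

#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

namespace {

struct Vec3 {
  double x, y, z;
};

inline Vec3 v3(double x, double y, double z) { return Vec3{x, y, z}; }
inline Vec3 sub(const Vec3 &a, const Vec3 &b) { return v3(a.x - b.x, a.y - b.y, a.z - b.z); }
inline Vec3 add(const Vec3 &a, const Vec3 &b) { return v3(a.x + b.x, a.y + b.y, a.z + b.z); }
inline Vec3 scl(const Vec3 &a, double s) { return v3(a.x * s, a.y * s, a.z * s); }
inline double dot(const Vec3 &a, const Vec3 &b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
inline Vec3 cross(const Vec3 &a, const Vec3 &b) {
  return v3(a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x);
}
inline double norm2(const Vec3 &a) { return dot(a, a); }

inline Vec3 rowvec(const NumericMatrix &M, int i) {
  return v3(M(i, 0), M(i, 1), M(i, 2));
}

// Closest point on triangle (a,b,c) to p; returns barycentric (u,v,w) with
// u+v+w=1, clamped to the triangle (Ericson, Real-Time Collision Detection).
inline void closestOnTriangle(const Vec3 &p, const Vec3 &a, const Vec3 &b,
                              const Vec3 &c, double &u, double &v, double &w) {
  Vec3 ab = sub(b, a), ac = sub(c, a), ap = sub(p, a);
  double d1 = dot(ab, ap), d2 = dot(ac, ap);
  if (d1 <= 0.0 && d2 <= 0.0) { u = 1.0; v = 0.0; w = 0.0; return; }
  Vec3 bp = sub(p, b);
  double d3 = dot(ab, bp), d4 = dot(ac, bp);
  if (d3 >= 0.0 && d4 <= d3) { u = 0.0; v = 1.0; w = 0.0; return; }
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double t = d1 / (d1 - d3);
    u = 1.0 - t; v = t; w = 0.0; return;
  }
  Vec3 cp = sub(p, c);
  double d5 = dot(ab, cp), d6 = dot(ac, cp);
  if (d6 >= 0.0 && d5 <= d6) { u = 0.0; v = 0.0; w = 1.0; return; }
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double t = d2 / (d2 - d6);
    u = 1.0 - t; v = 0.0; w = t; return;
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double t = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    u = 0.0; v = 1.0 - t; w = t; return;
  }
  double denom = 1.0 / (va + vb + vc);
  v = vb * denom;
  w = vc * denom;
  u = 1.0 - v - w;
}

}  // namespace

// For each query point, the globally nearest point on the mesh surface.
// V: nv x 3, F: nf x 3 (0-based), Q: nq x 3.
// Ties between triangles broken toward the lowest triangle index (the scan
// order, with strict improvement required), so results are deterministic.
// [[Rcpp::export(name = "cpp_closest_point_mesh")]]
List cpp_closest_point_mesh(NumericMatrix V, IntegerMatrix F, NumericMatrix Q) {
  const int nf = F.nrow(), nq = Q.nrow();
  std::vector<Vec3> a(nf), b(nf), c(nf), lo(nf), hi(nf);
  for (int t = 0; t < nf; ++t) {
    a[t] = rowvec(V, F(t, 0));
    b[t] = rowvec(V, F(t, 1));
    c[t] = rowvec(V, F(t, 2));
    lo[t] = v3(std::min({a[t].x, b[t].x, c[t].x}), std::min({a[t].y, b[t].y, c[t].y}),
               std::min({a[t].z, b[t].z, c[t].z}));
    hi[t] = v3(std::max({a[t].x, b[t].x, c[t].x}), std::max({a[t].y, b[t].y, c[t].y}),
               std::max({a[t].z, b[t].z, c[t].z}));
  }
  IntegerVector tri(nq);
  NumericMatrix bary(nq, 3), foot(nq, 3);
  NumericVector dist(nq);
  for (int q = 0; q < nq; ++q) {
    Vec3 p = rowvec(Q, q);
    // pass 1: exact minimum squared distance
    double best = R_PosInf;
    for (int t = 0; t < nf; ++t) {
      double dx = std::max({lo[t].x - p.x, 0.0, p.x - hi[t].x});
      double dy = std::max({lo[t].y - p.y, 0.0, p.y - hi[t].y});
      double dz = std::max({lo[t].z - p.z, 0.0, p.z - hi[t].z});
      if (dx * dx + dy * dy + dz * dz >= best) continue;
      double u, v, w;
      closestOnTriangle(p, a[t], b[t], c[t], u, v, w);
      Vec3 cp = add(scl(a[t], u), add(scl(b[t], v), scl(c[t], w)));
      double d2 = norm2(sub(p, cp));
      if (d2 < best) best = d2;
    }
    // pass 2: lowest triangle index within the tie tolerance, so equidistant
    // cases break deterministically *and* stably under rigid motion (exact
    // ties perturbed at machine precision still pick the same triangle)
    const double tol2 = best + 1e-9 * (1.0 + best);
    double bu = 0, bv = 0, bw = 0;
    Vec3 bp = p;
    int bt = -1;
    for (int t = 0; t < nf && bt < 0; ++t) {
      double dx = std::max({lo[t].x - p.x, 0.0, p.x - hi[t].x});
      double dy = std::max({lo[t].y - p.y, 0.0, p.y - hi[t].y});
      double dz = std::max({lo[t].z - p.z, 0.0, p.z - hi[t].z});
      if (dx * dx + dy * dy + dz * dz > tol2) continue;
      double u, v, w;
      closestOnTriangle(p, a[t], b[t], c[t], u, v, w);
      Vec3 cp = add(scl(a[t], u), add(scl(b[t], v), scl(c[t], w)));
      double d2 = norm2(sub(p, cp));
      if (d2 <= tol2) {
        bu = u; bv = v; bw = w; bp = cp; bt = t;
      }
    }
    tri[q] = bt;
    bary(q, 0) = bu; bary(q, 1) = bv; bary(q, 2) = bw;
    foot(q, 0) = bp.x; foot(q, 1) = bp.y; foot(q, 2) = bp.z;
    dist[q] = std::sqrt(norm2(sub(p, bp)));
  }
  return List::create(_["tri"] = tri, _["bary"] = bary, _["foot"] = foot,
                      _["dist"] = dist);
}

namespace {

// Segment (p,q) vs triangle (a,b,c) intersection (Moller-Trumbore with
// segment clamping). Used for the pairwise self-intersection scan; coplanar
// overlaps are not detected (documented limitation of the load-time check).
inline bool segTriangle(const Vec3 &p, const Vec3 &q, const Vec3 &a,
                        const Vec3 &b, const Vec3 &c) {
  const double eps = 1e-12;
  Vec3 dir = sub(q, p);
  Vec3 e1 = sub(b, a), e2 = sub(c, a);
  Vec3 h = cross(dir, e2);
  double det = dot(e1, h);
  if (std::fabs(det) < eps) return false;
  double inv = 1.0 / det;
  Vec3 s = sub(p, a);
  double u = inv * dot(s, h);
  if (u < eps || u > 1.0 - eps) return false;
  Vec3 qv = cross(s, e1);
  double v = inv * dot(dir, qv);
  if (v < eps || u + v > 1.0 - eps) return false;
  double t = inv * dot(e2, qv);
  return (t > eps && t < 1.0 - eps);
}

}  // namespace

// First pair of non-adjacent triangles whose edges pierce each other, or
// integer(0). O(n^2) with AABB rejection; meant for load-time validation of
// modest template meshes.
// [[Rcpp::export(name = "cpp_self_intersections")]]
IntegerVector cpp_self_intersections(NumericMatrix V, IntegerMatrix F) {
  const int nf = F.nrow();
  std::vector<Vec3> lo(nf), hi(nf);
  for (int t = 0; t < nf; ++t) {
    Vec3 a = rowvec(V, F(t, 0)), b = rowvec(V, F(t, 1)), c = rowvec(V, F(t, 2));
    lo[t] = v3(std::min({a.x, b.x, c.x}), std::min({a.y, b.y, c.y}), std::min({a.z, b.z, c.z}));
    hi[t] = v3(std::max({a.x, b.x, c.x}), std::max({a.y, b.y, c.y}), std::max({a.z, b.z, c.z}));
  }
  for (int s = 0; s < nf; ++s) {
    for (int t = s + 1; t < nf; ++t) {
      if (lo[s].x > hi[t].x || lo[t].x > hi[s].x || lo[s].y > hi[t].y ||
          lo[t].y > hi[s].y || lo[s].z > hi[t].z || lo[t].z > hi[s].z)
        continue;
      bool adjacent = false;
      for (int i = 0; i < 3 && !adjacent; ++i)
        for (int j = 0; j < 3; ++j)
          if (F(s, i) == F(t, j)) { adjacent = true; break; }
      if (adjacent) continue;
      Vec3 sa = rowvec(V, F(s, 0)), sb = rowvec(V, F(s, 1)), sc = rowvec(V, F(s, 2));
      Vec3 ta = rowvec(V, F(t, 0)), tb = rowvec(V, F(t, 1)), tc = rowvec(V, F(t, 2));
      bool hit = segTriangle(sa, sb, ta, tb, tc) || segTriangle(sb, sc, ta, tb, tc) ||
                 segTriangle(sc, sa, ta, tb, tc) || segTriangle(ta, tb, sa, sb, sc) ||
                 segTriangle(tb, tc, sa, sb, sc) || segTriangle(tc, ta, sa, sb, sc);
      if (hit) return IntegerVector::create(s, t);
    }
  }
  return IntegerVector(0);
}

// Tag a regular cell grid against a closed triangulated cage.
// Cells whose center lies within half a cell diagonal of the surface are
// BOUNDARY (1); a flood fill from the grid border through non-boundary cells
// marks EXTERIOR (2); the remainder is INTERIOR (0).  origin is the center of
// cell (0,0,0); h the cell size.  Also returns, per boundary cell, the closest
// cage triangle and barycentric weights (for the Dirichlet data), and the
// number of interior cells reachable from `seed` (world point), so the caller
// can detect a disconnected interior.
// [[Rcpp::export(name = "cpp_tag_grid")]]
List cpp_tag_grid(NumericMatrix V, IntegerMatrix F, IntegerVector dims,
                  NumericVector origin, double h, NumericVector seed) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t ncell = (R_xlen_t)nx * ny * nz;
  IntegerVector tags(ncell, 0);
  const double rad = 0.5 * h * std::sqrt(3.0);
  const int nf = F.nrow();

  auto idx = [&](int i, int j, int k) -> R_xlen_t {
    return (R_xlen_t)i + (R_xlen_t)nx * ((R_xlen_t)j + (R_xlen_t)ny * k);
  };

  // Boundary tagging: for each triangle, test cells in its (dilated) bbox.
  for (int t = 0; t < nf; ++t) {
    Vec3 a = rowvec(V, F(t, 0)), b = rowvec(V, F(t, 1)), c = rowvec(V, F(t, 2));
    double lx = std::min({a.x, b.x, c.x}) - rad, hx = std::max({a.x, b.x, c.x}) + rad;
    double ly = std::min({a.y, b.y, c.y}) - rad, hy = std::max({a.y, b.y, c.y}) + rad;
    double lz = std::min({a.z, b.z, c.z}) - rad, hz = std::max({a.z, b.z, c.z}) + rad;
    int i0 = std::max(0, (int)std::ceil((lx - origin[0]) / h));
    int i1 = std::min(nx - 1, (int)std::floor((hx - origin[0]) / h));
    int j0 = std::max(0, (int)std::ceil((ly - origin[1]) / h));
    int j1 = std::min(ny - 1, (int)std::floor((hy - origin[1]) / h));
    int k0 = std::max(0, (int)std::ceil((lz - origin[2]) / h));
    int k1 = std::min(nz - 1, (int)std::floor((hz - origin[2]) / h));
    for (int k = k0; k <= k1; ++k)
      for (int j = j0; j <= j1; ++j)
        for (int i = i0; i <= i1; ++i) {
          R_xlen_t id = idx(i, j, k);
          if (tags[id] == 1) continue;
          Vec3 p = v3(origin[0] + i * h, origin[1] + j * h, origin[2] + k * h);
          double u, v, w;
          closestOnTriangle(p, a, b, c, u, v, w);
          Vec3 cp = add(scl(a, u), add(scl(b, v), scl(c, w)));
          if (norm2(sub(p, cp)) <= rad * rad) tags[id] = 1;
        }
  }

  // Exterior flood fill from every border cell.
  std::queue<R_xlen_t> bfs;
  auto push_ext = [&](int i, int j, int k) {
    R_xlen_t id = idx(i, j, k);
    if (tags[id] == 0) { tags[id] = 2; bfs.push(id); }
  };
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) { push_ext(i, j, 0); push_ext(i, j, nz - 1); }
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) { push_ext(i, 0, k); push_ext(i, ny - 1, k); }
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) { push_ext(0, j, k); push_ext(nx - 1, j, k); }
  const int di[6] = {1, -1, 0, 0, 0, 0};
  const int dj[6] = {0, 0, 1, -1, 0, 0};
  const int dk[6] = {0, 0, 0, 0, 1, -1};
  while (!bfs.empty()) {
    R_xlen_t id = bfs.front(); bfs.pop();
    int i = (int)(id % nx), j = (int)((id / nx) % ny), k = (int)(id / ((R_xlen_t)nx * ny));
    for (int n = 0; n < 6; ++n) {
      int ii = i + di[n], jj = j + dj[n], kk = k + dk[n];
      if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
      push_ext(ii, jj, kk);
    }
  }

  // Boundary Dirichlet data: closest cage triangle + barycentric weights.
  std::vector<R_xlen_t> bcells;
  for (R_xlen_t id = 0; id < ncell; ++id)
    if (tags[id] == 1) bcells.push_back(id);
  const int nb = (int)bcells.size();
  IntegerVector bcell(nb), btri(nb);
  NumericMatrix bbary(nb, 3);
  for (int q = 0; q < nb; ++q) {
    R_xlen_t id = bcells[q];
    int i = (int)(id % nx), j = (int)((id / nx) % ny), k = (int)(id / ((R_xlen_t)nx * ny));
    Vec3 p = v3(origin[0] + i * h, origin[1] + j * h, origin[2] + k * h);
    double best = R_PosInf, bu = 0, bv = 0, bw = 0;
    int bt = -1;
    for (int t = 0; t < nf; ++t) {
      Vec3 a = rowvec(V, F(t, 0)), b = rowvec(V, F(t, 1)), c = rowvec(V, F(t, 2));
      double u, v, w;
      closestOnTriangle(p, a, b, c, u, v, w);
      Vec3 cp = add(scl(a, u), add(scl(b, v), scl(c, w)));
      double d2 = norm2(sub(p, cp));
      if (d2 < best) { best = d2; bu = u; bv = v; bw = w; bt = t; }
    }
    bcell[q] = (int)id; btri[q] = bt;
    bbary(q, 0) = bu; bbary(q, 1) = bv; bbary(q, 2) = bw;
  }

  // Interior connectivity from the seed point.
  R_xlen_t n_interior = 0, n_reached = 0;
  for (R_xlen_t id = 0; id < ncell; ++id)
    if (tags[id] == 0) ++n_interior;
  int si = (int)std::lround((seed[0] - origin[0]) / h);
  int sj = (int)std::lround((seed[1] - origin[1]) / h);
  int sk = (int)std::lround((seed[2] - origin[2]) / h);
  if (si >= 0 && sj >= 0 && sk >= 0 && si < nx && sj < ny && sk < nz &&
      tags[idx(si, sj, sk)] == 0) {
    std::vector<char> seen(ncell, 0);
    std::queue<R_xlen_t> q2;
    q2.push(idx(si, sj, sk));
    seen[idx(si, sj, sk)] = 1;
    while (!q2.empty()) {
      R_xlen_t id = q2.front(); q2.pop();
      ++n_reached;
      int i = (int)(id % nx), j = (int)((id / nx) % ny), k = (int)(id / ((R_xlen_t)nx * ny));
      for (int n = 0; n < 6; ++n) {
        int ii = i + di[n], jj = j + dj[n], kk = k + dk[n];
        if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
        R_xlen_t nid = idx(ii, jj, kk);
        if (tags[nid] == 0 && !seen[nid]) { seen[nid] = 1; q2.push(nid); }
      }
    }
  }
  return List::create(_["tags"] = tags, _["bcell"] = bcell, _["btri"] = btri,
                      _["bbary"] = bbary, _["n_interior"] = (double)n_interior,
                      _["n_reached"] = (double)n_reached);
}

// Discrete-harmonic solve on INTERIOR cells with Dirichlet data on BOUNDARY
// cells: 6-neighbour Laplace stencil, conjugate gradients (the system is SPD),
// one right-hand side per cage vertex.  `bvalues` is ncell x ncage, nonzero
// only at boundary cells.  Returns ncell x ncage fields (exterior rows zero)
// plus the worst relative residual.
// [[Rcpp::export(name = "cpp_solve_laplace")]]
List cpp_solve_laplace(IntegerVector dims, IntegerVector tags,
                       NumericMatrix bvalues, double tol, int maxit) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t ncell = (R_xlen_t)nx * ny * nz;
  const int ncage = bvalues.ncol();

  std::vector<R_xlen_t> cell_of;          // unknown -> cell
  std::vector<int> unk_of(ncell, -1);     // cell -> unknown (-1 if not)
  for (R_xlen_t id = 0; id < ncell; ++id)
    if (tags[id] == 0) { unk_of[id] = (int)cell_of.size(); cell_of.push_back(id); }
  const int n = (int)cell_of.size();

  // Precompute neighbour structure: unknown neighbours and boundary cells.
  std::vector<int> nb_unk(6 * (size_t)n, -1);
  std::vector<R_xlen_t> nb_bnd(6 * (size_t)n, -1);
  const int di[6] = {1, -1, 0, 0, 0, 0};
  const int dj[6] = {0, 0, 1, -1, 0, 0};
  const int dk[6] = {0, 0, 0, 0, 1, -1};
  for (int u = 0; u < n; ++u) {
    R_xlen_t id = cell_of[u];
    int i = (int)(id % nx), j = (int)((id / nx) % ny), k = (int)(id / ((R_xlen_t)nx * ny));
    for (int m = 0; m < 6; ++m) {
      int ii = i + di[m], jj = j + dj[m], kk = k + dk[m];
      if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
      R_xlen_t nid = (R_xlen_t)ii + (R_xlen_t)nx * ((R_xlen_t)jj + (R_xlen_t)ny * kk);
      if (tags[nid] == 0) nb_unk[6 * (size_t)u + m] = unk_of[nid];
      else if (tags[nid] == 1) nb_bnd[6 * (size_t)u + m] = nid;
    }
  }

  // Block CG: all cage-vertex fields share each stencil sweep (the sweep is
  // memory-bound, so batching right-hand sides is nearly free).  Per-column
  // scalars keep the iterations mathematically independent.
  const int nc = ncage;
  const size_t nn = (size_t)n * nc;
  std::vector<double> x(nn, 0.0), r(nn), p(nn), Ap(nn), bb(nn, 0.0);
  for (int u = 0; u < n; ++u) {
    const size_t base = 6 * (size_t)u;
    for (int m = 0; m < 6; ++m) {
      R_xlen_t bc = nb_bnd[base + m];
      if (bc >= 0)
        for (int j = 0; j < nc; ++j) bb[(size_t)u * nc + j] += bvalues(bc, j);
    }
  }
  std::vector<double> bnorm2(nc, 0.0), rs(nc), alpha(nc), beta(nc), pAp(nc);
  for (int u = 0; u < n; ++u)
    for (int j = 0; j < nc; ++j) {
      double v = bb[(size_t)u * nc + j];
      bnorm2[j] += v * v;
    }
  r = bb;
  p = r;
  rs = bnorm2;
  auto done = [&]() {
    for (int j = 0; j < nc; ++j)
      if (bnorm2[j] > 0.0 && rs[j] > tol * tol * bnorm2[j]) return false;
    return true;
  };
  for (int it = 0; it < maxit && !done(); ++it) {
    for (int u = 0; u < n; ++u) {
      const size_t base = 6 * (size_t)u;
      double *out = &Ap[(size_t)u * nc];
      const double *in = &p[(size_t)u * nc];
      for (int j = 0; j < nc; ++j) out[j] = 6.0 * in[j];
      for (int m = 0; m < 6; ++m) {
        int w = nb_unk[base + m];
        if (w >= 0) {
          const double *nbp = &p[(size_t)w * nc];
          for (int j = 0; j < nc; ++j) out[j] -= nbp[j];
        }
      }
    }
    std::fill(pAp.begin(), pAp.end(), 0.0);
    for (size_t u = 0; u < (size_t)n; ++u)
      for (int j = 0; j < nc; ++j) pAp[j] += p[u * nc + j] * Ap[u * nc + j];
    for (int j = 0; j < nc; ++j)
      alpha[j] = (pAp[j] > 0.0) ? rs[j] / pAp[j] : 0.0;
    std::vector<double> rs_new(nc, 0.0);
    for (size_t u = 0; u < (size_t)n; ++u)
      for (int j = 0; j < nc; ++j) {
        x[u * nc + j] += alpha[j] * p[u * nc + j];
        r[u * nc + j] -= alpha[j] * Ap[u * nc + j];
        rs_new[j] += r[u * nc + j] * r[u * nc + j];
      }
    for (int j = 0; j < nc; ++j)
      beta[j] = (rs[j] > 0.0) ? rs_new[j] / rs[j] : 0.0;
    rs = rs_new;
    for (size_t u = 0; u < (size_t)n; ++u)
      for (int j = 0; j < nc; ++j)
        p[u * nc + j] = r[u * nc + j] + beta[j] * p[u * nc + j];
  }
  double worst_rel = 0.0;
  for (int j = 0; j < nc; ++j)
    if (bnorm2[j] > 0.0)
      worst_rel = std::max(worst_rel, std::sqrt(rs[j] / bnorm2[j]));
  NumericMatrix fields(ncell, ncage);
  for (int u = 0; u < n; ++u)
    for (int j = 0; j < nc; ++j) fields(cell_of[u], j) = x[(size_t)u * nc + j];
  for (R_xlen_t id = 0; id < ncell; ++id)
    if (tags[id] == 1)
      for (int j = 0; j < nc; ++j) fields(id, j) = bvalues(id, j);
  return List::create(_["fields"] = fields, _["residual"] = worst_rel);
}

// Trilinear interpolation of per-cell fields at arbitrary points; cells
// tagged EXTERIOR (2) contribute value 0.  origin = center of cell (0,0,0).
// [[Rcpp::export(name = "cpp_trilinear_sample")]]
NumericMatrix cpp_trilinear_sample(IntegerVector dims, NumericVector origin,
                                   double h, NumericMatrix fields,
                                   IntegerVector tags, NumericMatrix P) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int np = P.nrow(), nc = fields.ncol();
  NumericMatrix out(np, nc);
  for (int q = 0; q < np; ++q) {
    double u = (P(q, 0) - origin[0]) / h;
    double v = (P(q, 1) - origin[1]) / h;
    double w = (P(q, 2) - origin[2]) / h;
    int i0 = (int)std::floor(u), j0 = (int)std::floor(v), k0 = (int)std::floor(w);
    double fu = u - i0, fv = v - j0, fw = w - k0;
    for (int dk = 0; dk < 2; ++dk)
      for (int dj = 0; dj < 2; ++dj)
        for (int di = 0; di < 2; ++di) {
          int i = i0 + di, j = j0 + dj, k = k0 + dk;
          if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) continue;
          R_xlen_t id = (R_xlen_t)i + (R_xlen_t)nx * ((R_xlen_t)j + (R_xlen_t)ny * k);
          if (tags[id] == 2) continue;
          double wt = (di ? fu : 1.0 - fu) * (dj ? fv : 1.0 - fv) * (dk ? fw : 1.0 - fw);
          if (wt == 0.0) continue;
          for (int cidx = 0; cidx < nc; ++cidx)
            out(q, cidx) += wt * fields(id, cidx);
        }
  }
  return out;
}

// Even-odd parity voxelization of a watertight mesh: a voxel is labeled iff
// its center is inside.  Implemented by casting one +x ray per (j,k) voxel
// row through voxel centers; the ray origin is deterministically perturbed by
// a sub-voxel irrational offset in y/z so edge-aligned hits are generic.
// [[Rcpp::export(name = "cpp_voxelize")]]
IntegerVector cpp_voxelize(NumericMatrix V, IntegerMatrix F, IntegerVector dims,
                           NumericVector spacing, NumericVector origin) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int nf = F.nrow();
  const double pey = 7.1e-8 * spacing[1], pez = 3.9e-8 * spacing[2];
  std::vector<std::vector<double>> rows((size_t)ny * nz);
  for (int t = 0; t < nf; ++t) {
    Vec3 a = rowvec(V, F(t, 0)), b = rowvec(V, F(t, 1)), c = rowvec(V, F(t, 2));
    double ly = std::min({a.y, b.y, c.y}), hy = std::max({a.y, b.y, c.y});
    double lz = std::min({a.z, b.z, c.z}), hz = std::max({a.z, b.z, c.z});
    int j0 = std::max(0, (int)std::ceil((ly - origin[1] - pey) / spacing[1]));
    int j1 = std::min(ny - 1, (int)std::floor((hy - origin[1] - pey) / spacing[1]));
    int k0 = std::max(0, (int)std::ceil((lz - origin[2] - pez) / spacing[2]));
    int k1 = std::min(nz - 1, (int)std::floor((hz - origin[2] - pez) / spacing[2]));
    double e1y = b.y - a.y, e1z = b.z - a.z, e2y = c.y - a.y, e2z = c.z - a.z;
    double det = e1y * e2z - e1z * e2y;
    if (det == 0.0) continue;  // edge-on triangle: neighbours carry the parity
    double inv = 1.0 / det;
    for (int k = k0; k <= k1; ++k) {
      double zc = origin[2] + k * spacing[2] + pez;
      for (int j = j0; j <= j1; ++j) {
        double yc = origin[1] + j * spacing[1] + pey;
        double sy = yc - a.y, sz = zc - a.z;
        double u = (sy * e2z - sz * e2y) * inv;
        double v = (e1y * sz - e1z * sy) * inv;
        if (u <= 0.0 || v <= 0.0 || u + v >= 1.0) continue;
        double xhit = a.x + u * (b.x - a.x) + v * (c.x - a.x);
        rows[(size_t)j + (size_t)ny * k].push_back(xhit);
      }
    }
  }
  IntegerVector mask((R_xlen_t)nx * ny * nz, 0);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      std::vector<double> &xs = rows[(size_t)j + (size_t)ny * k];
      if (xs.empty()) continue;
      std::sort(xs.begin(), xs.end());
      for (int i = 0; i < nx; ++i) {
        double xc = origin[0] + i * spacing[0];
        size_t above = xs.end() - std::upper_bound(xs.begin(), xs.end(), xc);
        if (above & 1)
          mask[(R_xlen_t)i + (R_xlen_t)nx * ((R_xlen_t)j + (R_xlen_t)ny * k)] = 1;
      }
    }
  return mask;
}
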