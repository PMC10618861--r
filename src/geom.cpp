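// Triangle-mesh geometry kernel: tri-tri intersection, AABB-tree queries,
// point-in-mesh, mesh-mesh minimum distance, and the exhaustive joint sweep.
// All meshes are (n x 3) vertex matrices plus (m x 3) 1-based face matrices.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

namespace {

const double EPS = 1e-12;

struct V3 {
  double x, y, z;
};
inline V3 v3(double x, double y, double z) { return V3{x, y, z}; }
inline V3 sub(const V3 &a, const V3 &b) { return v3(a.x - b.x, a.y - b.y, a.z - b.z); }
inline V3 add(const V3 &a, const V3 &b) { return v3(a.x + b.x, a.y + b.y, a.z + b.z); }
inline V3 mul(const V3 &a, double s) { return v3(a.x * s, a.y * s, a.z * s); }
inline double dot(const V3 &a, const V3 &b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
inline V3 cross(const V3 &a, const V3 &b) {
  return v3(a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x);
}
inline double norm2(const V3 &a) { return dot(a, a); }

struct Mesh {
  std::vector<V3> v;
  std::vector<std::array<int, 3>> f;
};

Mesh as_mesh(const NumericMatrix &V, const IntegerMatrix &F) {
  Mesh m;
  m.v.resize(V.nrow());
  for (int i = 0; i < V.nrow(); ++i) m.v[i] = v3(V(i, 0), V(i, 1), V(i, 2));
  m.f.resize(F.nrow());
  for (int i = 0; i < F.nrow(); ++i) m.f[i] = {F(i, 0) - 1, F(i, 1) - 1, F(i, 2) - 1};
  return m;
}

// ---------------------------------------------------------------- tri-tri
// Moller (1997) interval-overlap triangle-triangle intersection test,
// including the coplanar branch. Returns true for crossing or touching
// (within EPS) triangles.

inline void isect2(double VV0, double VV1, double VV2, double D0, double D1, double D2,
                   double *isect0, double *isect1) {
  double t0 = VV0 + (VV1 - VV0) * D0 / (D0 - D1);
  double t1 = VV0 + (VV2 - VV0) * D0 / (D0 - D2);
  *isect0 = std::min(t0, t1);
  *isect1 = std::max(t0, t1);
}

// interval for a triangle against the intersection line; returns false if
// the configuration is coplanar (caller handles it)
inline bool compute_intervals(double VV0, double VV1, double VV2, double D0, double D1,
                              double D2, double D0D1, double D0D2, double *i0, double *i1) {
  if (D0D1 > 0.0) {
    // D0, D1 same side, D2 on the other
    isect2(VV2, VV0, VV1, D2, D0, D1, i0, i1);
  } else if (D0D2 > 0.0) {
    isect2(VV1, VV0, VV2, D1, D0, D2, i0, i1);
  } else if (D1 * D2 > 0.0 || D0 != 0.0) {
    isect2(VV0, VV1, VV2, D0, D1, D2, i0, i1);
  } else if (D1 != 0.0) {
    isect2(VV1, VV0, VV2, D1, D0, D2, i0, i1);
  } else if (D2 != 0.0) {
    isect2(VV2, VV0, VV1, D2, D0, D1, i0, i1);
  } else {
    return false;  // coplanar
  }
  return true;
}

// 2D helpers for the coplanar case
inline bool edge_edge_test(double ax, double ay, const double *v0, const double *u0,
                           const double *u1) {
  double bx = u0[0] - u1[0];
  double by = u0[1] - u1[1];
  double cx = v0[0] - u0[0];
  double cy = v0[1] - u0[1];
  double f = ay * bx - ax * by;
  double d = by * cx - bx * cy;
  if ((f > 0 && d >= 0 && d <= f) || (f < 0 && d <= 0 && d >= f)) {
    double e = ax * cy - ay * cx;
    if (f > 0) {
      if (e >= 0 && e <= f) return true;
    } else {
      if (e <= 0 && e >= f) return true;
    }
  }
  return false;
}

inline bool edge_against_tri_edges(const double *v0, const double *v1, const double *u0,
                                   const double *u1, const double *u2) {
  double ax = v1[0] - v0[0];
  double ay = v1[1] - v0[1];
  if (edge_edge_test(ax, ay, v0, u0, u1)) return true;
  if (edge_edge_test(ax, ay, v0, u1, u2)) return true;
  if (edge_edge_test(ax, ay, v0, u2, u0)) return true;
  return false;
}

inline bool point_in_tri2d(const double *v0, const double *u0, const double *u1,
                           const double *u2) {
  double a = u1[1] - u0[1];
  double b = -(u1[0] - u0[0]);
  double c = -a * u0[0] - b * u0[1];
  double d0 = a * v0[0] + b * v0[1] + c;

  a = u2[1] - u1[1];
  b = -(u2[0] - u1[0]);
  c = -a * u1[0] - b * u1[1];
  double d1 = a * v0[0] + b * v0[1] + c;

  a = u0[1] - u2[1];
  b = -(u0[0] - u2[0]);
  c = -a * u2[0] - b * u2[1];
  double d2 = a * v0[0] + b * v0[1] + c;

  return (d0 * d1 > 0.0 && d0 * d2 > 0.0);
}

bool coplanar_tri_tri(const V3 &N, const V3 &V0, const V3 &V1, const V3 &V2, const V3 &U0,
                      const V3 &U1, const V3 &U2) {
  double A[3] = {std::fabs(N.x), std::fabs(N.y), std::fabs(N.z)};
  int i0, i1;
  if (A[0] > A[1]) {
    if (A[0] > A[2]) { i0 = 1; i1 = 2; }
    else { i0 = 0; i1 = 1; }
  } else {
    if (A[2] > A[1]) { i0 = 0; i1 = 1; }
    else { i0 = 0; i1 = 2; }
  }
  auto pick = [&](const V3 &p, double *out) {
    const double c[3] = {p.x, p.y, p.z};
    out[0] = c[i0];
    out[1] = c[i1];
  };
  double v0[2], v1[2], v2[2], u0[2], u1[2], u2[2];
  pick(V0, v0); pick(V1, v1); pick(V2, v2);
  pick(U0, u0); pick(U1, u1); pick(U2, u2);

  if (edge_against_tri_edges(v0, v1, u0, u1, u2)) return true;
  if (edge_against_tri_edges(v1, v2, u0, u1, u2)) return true;
  if (edge_against_tri_edges(v2, v0, u0, u1, u2)) return true;
  if (point_in_tri2d(v0, u0, u1, u2)) return true;
  if (point_in_tri2d(u0, v0, v1, v2)) return true;
  return false;
}

bool tri_tri_intersect(const V3 &V0, const V3 &V1, const V3 &V2, const V3 &U0, const V3 &U1,
                       const V3 &U2) {
  V3 E1 = sub(V1, V0), E2 = sub(V2, V0);
  V3 N1 = cross(E1, E2);
  double d1 = -dot(N1, V0);
  double du0 = dot(N1, U0) + d1;
  double du1 = dot(N1, U1) + d1;
  double du2 = dot(N1, U2) + d1;
  double eps1 = EPS * std::sqrt(norm2(N1));
  if (std::fabs(du0) < eps1) du0 = 0.0;
  if (std::fabs(du1) < eps1) du1 = 0.0;
  if (std::fabs(du2) < eps1) du2 = 0.0;
  double du0du1 = du0 * du1, du0du2 = du0 * du2;
  if (du0du1 > 0.0 && du0du2 > 0.0) return false;

  E1 = sub(U1, U0); E2 = sub(U2, U0);
  V3 N2 = cross(E1, E2);
  double d2 = -dot(N2, U0);
  double dv0 = dot(N2, V0) + d2;
  double dv1 = dot(N2, V1) + d2;
  double dv2 = dot(N2, V2) + d2;
  double eps2 = EPS * std::sqrt(norm2(N2));
  if (std::fabs(dv0) < eps2) dv0 = 0.0;
  if (std::fabs(dv1) < eps2) dv1 = 0.0;
  if (std::fabs(dv2) < eps2) dv2 = 0.0;
  double dv0dv1 = dv0 * dv1, dv0dv2 = dv0 * dv2;
  if (dv0dv1 > 0.0 && dv0dv2 > 0.0) return false;

  V3 D = cross(N1, N2);
  double max = std::fabs(D.x);
  int index = 0;
  double bb = std::fabs(D.y), cc = std::fabs(D.z);
  if (bb > max) { max = bb; index = 1; }
  if (cc > max) { max = cc; index = 2; }

  double vp0, vp1, vp2, up0, up1, up2;
  if (index == 0) { vp0 = V0.x; vp1 = V1.x; vp2 = V2.x; up0 = U0.x; up1 = U1.x; up2 = U2.x; }
  else if (index == 1) { vp0 = V0.y; vp1 = V1.y; vp2 = V2.y; up0 = U0.y; up1 = U1.y; up2 = U2.y; }
  else { vp0 = V0.z; vp1 = V1.z; vp2 = V2.z; up0 = U0.z; up1 = U1.z; up2 = U2.z; }

  double isect1[2], isect2v[2];
  if (!compute_intervals(vp0, vp1, vp2, dv0, dv1, dv2, dv0dv1, dv0dv2, &isect1[0], &isect1[1]))
    return coplanar_tri_tri(N1, V0, V1, V2, U0, U1, U2);
  if (!compute_intervals(up0, up1, up2, du0, du1, du2, du0du1, du0du2, &isect2v[0], &isect2v[1]))
    return coplanar_tri_tri(N1, V0, V1, V2, U0, U1, U2);

  if (isect1[1] < isect2v[0] || isect2v[1] < isect1[0]) return false;
  return true;
}

// ------------------------------------------------------------------- AABB
struct Box {
  double lo[3], hi[3];
};

inline Box tri_box(const Mesh &m, int t) {
  Box b;
  const V3 &a = m.v[m.f[t][0]];
  const V3 &bb = m.v[m.f[t][1]];
  const V3 &c = m.v[m.f[t][2]];
  b.lo[0] = std::min({a.x, bb.x, c.x}); b.hi[0] = std::max({a.x, bb.x, c.x});
  b.lo[1] = std::min({a.y, bb.y, c.y}); b.hi[1] = std::max({a.y, bb.y, c.y});
  b.lo[2] = std::min({a.z, bb.z, c.z}); b.hi[2] = std::max({a.z, bb.z, c.z});
  return b;
}

inline bool box_overlap(const Box &a, const Box &b) {
  for (int k = 0; k < 3; ++k)
    if (a.hi[k] < b.lo[k] || b.hi[k] < a.lo[k]) return false;
  return true;
}

inline double box_dist2(const Box &a, const Box &b) {
  double d2 = 0.0;
  for (int k = 0; k < 3; ++k) {
    double d = std::max({0.0, b.lo[k] - a.hi[k], a.lo[k] - b.hi[k]});
    d2 += d * d;
  }
  return d2;
}

// static median-split AABB tree over triangles
struct BVH {
  struct Node {
    Box box;
    int left, right;   // children, -1 at leaf
    int begin, end;    // triangle index range (into order) for leaves
  };
  std::vector<Node> nodes;
  std::vector<int> order;
  std::vector<Box> tbox;

  void build(const Mesh &m) {
    int n = (int)m.f.size();
    order.resize(n);
    tbox.resize(n);
    for (int i = 0; i < n; ++i) {
      order[i] = i;
      tbox[i] = tri_box(m, i);
    }
    nodes.clear();
    nodes.reserve(2 * n);
    build_rec(0, n);
  }

  int build_rec(int begin, int end) {
    Node nd;
    nd.box.lo[0] = nd.box.lo[1] = nd.box.lo[2] = 1e300;
    nd.box.hi[0] = nd.box.hi[1] = nd.box.hi[2] = -1e300;
    for (int i = begin; i < end; ++i) {
      const Box &b = tbox[order[i]];
      for (int k = 0; k < 3; ++k) {
        nd.box.lo[k] = std::min(nd.box.lo[k], b.lo[k]);
        nd.box.hi[k] = std::max(nd.box.hi[k], b.hi[k]);
      }
    }
    int id = (int)nodes.size();
    nodes.push_back(nd);
    if (end - begin <= 4) {
      nodes[id].left = nodes[id].right = -1;
      nodes[id].begin = begin;
      nodes[id].end = end;
      return id;
    }
    int axis = 0;
    double ext = nd.box.hi[0] - nd.box.lo[0];
    for (int k = 1; k < 3; ++k) {
      double e = nd.box.hi[k] - nd.box.lo[k];
      if (e > ext) { ext = e; axis = k; }
    }
    int mid = (begin + end) / 2;
    std::nth_element(order.begin() + begin, order.begin() + mid, order.begin() + end,
                     [&](int a, int b) {
                       return tbox[a].lo[axis] + tbox[a].hi[axis] <
                              tbox[b].lo[axis] + tbox[b].hi[axis];
                     });
    int l = build_rec(begin, mid);
    int r = build_rec(mid, end);
    nodes[id].left = l;
    nodes[id].right = r;
    nodes[id].begin = nodes[id].end = -1;
    return id;
  }

  // does triangle (a,b,c) with box qb intersect any triangle of mesh m?
  bool hit(const Mesh &m, const Box &qb, const V3 &a, const V3 &b, const V3 &c) const {
    if (nodes.empty()) return false;
    std::vector<int> stack{0};
    while (!stack.empty()) {
      int id = stack.back();
      stack.pop_back();
      const Node &nd = nodes[id];
      if (!box_overlap(nd.box, qb)) continue;
      if (nd.left < 0) {
        for (int i = nd.begin; i < nd.end; ++i) {
          int t = order[i];
          if (!box_overlap(tbox[t], qb)) continue;
          if (tri_tri_intersect(a, b, c, m.v[m.f[t][0]], m.v[m.f[t][1]], m.v[m.f[t][2]]))
            return true;
        }
      } else {
        stack.push_back(nd.left);
        stack.push_back(nd.right);
      }
    }
    return false;
  }
};

// -------------------------------------------------------- point in mesh
// parity ray cast; retries along alternative directions on near-degenerate
// hits (edge grazes)
bool ray_hits(const V3 &orig, const V3 &dir, const V3 &a, const V3 &b, const V3 &c,
              bool &degenerate) {
  V3 e1 = sub(b, a), e2 = sub(c, a);
  V3 p = cross(dir, e2);
  double det = dot(e1, p);
  double scale = std::sqrt(norm2(e1) * norm2(e2));
  if (std::fabs(det) < 1e-14 * scale) return false;
  double inv = 1.0 / det;
  V3 tv = sub(orig, a);
  double u = dot(tv, p) * inv;
  if (u < 0.0 || u > 1.0) return false;
  V3 q = cross(tv, e1);
  double v = dot(dir, q) * inv;
  if (v < 0.0 || u + v > 1.0) return false;
  double t = dot(e2, q) * inv;
  if (t <= 0.0) return false;
  double tol = 1e-9;
  if (u < tol || v < tol || u + v > 1.0 - tol || t < tol) degenerate = true;
  return true;
}

bool point_inside(const Mesh &m, const V3 &p) {
  static const double dirs[3][3] = {{0.5703, 0.2712, 0.7741},
                                    {-0.3127, 0.8391, 0.4454},
                                    {0.1091, -0.5527, 0.8262}};
  for (int trial = 0; trial < 3; ++trial) {
    V3 d = v3(dirs[trial][0], dirs[trial][1], dirs[trial][2]);
    int count = 0;
    bool degen = false;
    for (size_t t = 0; t < m.f.size(); ++t) {
      if (ray_hits(p, d, m.v[m.f[t][0]], m.v[m.f[t][1]], m.v[m.f[t][2]], degen)) ++count;
      if (degen) break;
    }
    if (!degen) return (count % 2) == 1;
  }
  // all rays degenerate: fall back to last parity anyway
  V3 d = v3(dirs[0][0], dirs[0][1], dirs[0][2]);
  int count = 0;
  bool degen = false;
  for (size_t t = 0; t < m.f.size(); ++t)
    if (ray_hits(p, d, m.v[m.f[t][0]], m.v[m.f[t][1]], m.v[m.f[t][2]], degen)) ++count;
  return (count % 2) == 1;
}

bool meshes_intersect_bvh(const Mesh &A, const Mesh &B, const BVH &bvhB) {
  // global box reject
  Box ba, bb = bvhB.nodes.empty() ? Box{{0, 0, 0}, {0, 0, 0}} : bvhB.nodes[0].box;
  ba.lo[0] = ba.lo[1] = ba.lo[2] = 1e300;
  ba.hi[0] = ba.hi[1] = ba.hi[2] = -1e300;
  for (const V3 &p : A.v) {
    ba.lo[0] = std::min(ba.lo[0], p.x); ba.hi[0] = std::max(ba.hi[0], p.x);
    ba.lo[1] = std::min(ba.lo[1], p.y); ba.hi[1] = std::max(ba.hi[1], p.y);
    ba.lo[2] = std::min(ba.lo[2], p.z); ba.hi[2] = std::max(ba.hi[2], p.z);
  }
  if (!box_overlap(ba, bb)) return false;
  for (size_t t = 0; t < A.f.size(); ++t) {
    const V3 &a = A.v[A.f[t][0]];
    const V3 &b = A.v[A.f[t][1]];
    const V3 &c = A.v[A.f[t][2]];
    Box qb;
    qb.lo[0] = std::min({a.x, b.x, c.x}); qb.hi[0] = std::max({a.x, b.x, c.x});
    qb.lo[1] = std::min({a.y, b.y, c.y}); qb.hi[1] = std::max({a.y, b.y, c.y});
    qb.lo[2] = std::min({a.z, b.z, c.z}); qb.hi[2] = std::max({a.z, b.z, c.z});
    if (bvhB.hit(B, qb, a, b, c)) return true;
  }
  // no surface crossing: containment (either interior holds the other)
  if (!A.v.empty() && point_inside(B, A.v[0])) return true;
  if (!B.v.empty() && point_inside(A, B.v[0])) return true;
  return false;
}

// ------------------------------------------------- distances (point/seg/tri)
double point_tri_dist2(const V3 &p, const V3 &a, const V3 &b, const V3 &c) {
  // Ericson, Real-Time Collision Detection, closest point on triangle
  V3 ab = sub(b, a), ac = sub(c, a), ap = sub(p, a);
  double d1 = dot(ab, ap), d2 = dot(ac, ap);
  if (d1 <= 0.0 && d2 <= 0.0) return norm2(ap);
  V3 bp = sub(p, b);
  double d3 = dot(ab, bp), d4 = dot(ac, bp);
  if (d3 >= 0.0 && d4 <= d3) return norm2(bp);
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double t = d1 / (d1 - d3);
    return norm2(sub(p, add(a, mul(ab, t))));
  }
  V3 cp = sub(p, c);
  double d5 = dot(ab, cp), d6 = dot(ac, cp);
  if (d6 >= 0.0 && d5 <= d6) return norm2(cp);
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double t = d2 / (d2 - d6);
    return norm2(sub(p, add(a, mul(ac, t))));
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double t = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    return norm2(sub(p, add(b, mul(sub(c, b), t))));
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  return norm2(sub(p, add(a, add(mul(ab, v), mul(ac, w)))));
}

double seg_seg_dist2(const V3 &p1, const V3 &q1, const V3 &p2, const V3 &q2) {
  V3 d1 = sub(q1, p1), d2 = sub(q2, p2), r = sub(p1, p2);
  double a = norm2(d1), e = norm2(d2), f = dot(d2, r);
  double s, t;
  if (a <= EPS && e <= EPS) return norm2(r);
  if (a <= EPS) {
    s = 0.0;
    t = std::min(1.0, std::max(0.0, f / e));
  } else {
    double c = dot(d1, r);
    if (e <= EPS) {
      t = 0.0;
      s = std::min(1.0, std::max(0.0, -c / a));
    } else {
      double b = dot(d1, d2);
      double denom = a * e - b * b;
      s = denom > EPS * a * e ? std::min(1.0, std::max(0.0, (b * f - c * e) / denom)) : 0.0;
      t = (b * s + f) / e;
      if (t < 0.0) {
        t = 0.0;
        s = std::min(1.0, std::max(0.0, -c / a));
      } else if (t > 1.0) {
        t = 1.0;
        s = std::min(1.0, std::max(0.0, (b - c) / a));
      }
    }
  }
  V3 c1 = add(p1, mul(d1, s)), c2 = add(p2, mul(d2, t));
  return norm2(sub(c1, c2));
}

double tri_tri_dist2(const V3 *t1, const V3 *t2) {
  double best = 1e300;
  for (int i = 0; i < 3; ++i) {
    best = std::min(best, point_tri_dist2(t1[i], t2[0], t2[1], t2[2]));
    best = std::min(best, point_tri_dist2(t2[i], t1[0], t1[1], t1[2]));
  }
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j)
      best = std::min(best, seg_seg_dist2(t1[i], t1[(i + 1) % 3], t2[j], t2[(j + 1) % 3]));
  return best;
}

}  // namespace

// [[Rcpp::export]]
bool cpp_meshes_intersect(NumericMatrix VA, IntegerMatrix FA, NumericMatrix VB,
                          IntegerMatrix FB) {
  Mesh A = as_mesh(VA, FA), B = as_mesh(VB, FB);
  BVH bvh;
  bvh.build(B);
  return meshes_intersect_bvh(A, B, bvh);
}

// [[Rcpp::export]]
LogicalVector cpp_points_in_mesh(NumericMatrix P, NumericMatrix V, IntegerMatrix F) {
  Mesh m = as_mesh(V, F);
  LogicalVector out(P.nrow());
  for (int i = 0; i < P.nrow(); ++i)
    out[i] = point_inside(m, v3(P(i, 0), P(i, 1), P(i, 2)));
  return out;
}

// [[Rcpp::export]]
double cpp_min_distance(NumericMatrix VA, IntegerMatrix FA, NumericMatrix VB,
                        IntegerMatrix FB) {
  Mesh A = as_mesh(VA, FA), B = as_mesh(VB, FB);
  std::vector<Box> boxA(A.f.size()), boxB(B.f.size());
  for (size_t i = 0; i < A.f.size(); ++i) boxA[i] = tri_box(A, i);
  for (size_t i = 0; i < B.f.size(); ++i) boxB[i] = tri_box(B, i);
  double best = 1e300;
  for (size_t i = 0; i < A.f.size(); ++i) {
    V3 t1[3] = {A.v[A.f[i][0]], A.v[A.f[i][1]], A.v[A.f[i][2]]};
    for (size_t j = 0; j < B.f.size(); ++j) {
      if (box_dist2(boxA[i], boxB[j]) >= best) continue;
      V3 t2[3] = {B.v[B.f[j][0]], B.v[B.f[j][1]], B.v[B.f[j][2]]};
      best = std::min(best, tri_tri_dist2(t1, t2));
      if (best <= 0.0) return 0.0;
    }
  }
  return std::sqrt(best);
}

// count triangle pairs that intersect while sharing no vertex
// [[Rcpp::export]]
int cpp_self_intersections(NumericMatrix V, IntegerMatrix F) {
  Mesh m = as_mesh(V, F);
  std::vector<Box> boxes(m.f.size());
  for (size_t i = 0; i < m.f.size(); ++i) boxes[i] = tri_box(m, i);
  int bad = 0;
  for (size_t i = 0; i < m.f.size(); ++i) {
    for (size_t j = i + 1; j < m.f.size(); ++j) {
      if (!box_overlap(boxes[i], boxes[j])) continue;
      bool shared = false;
      for (int a = 0; a < 3 && !shared; ++a)
        for (int b = 0; b < 3; ++b)
          if (m.f[i][a] == m.f[j][b]) { shared = true; break; }
      if (shared) continue;
      if (tri_tri_intersect(m.v[m.f[i][0]], m.v[m.f[i][1]], m.v[m.f[i][2]],
                            m.v[m.f[j][0]], m.v[m.f[j][1]], m.v[m.f[j][2]]))
        ++bad;
    }
  }
  return bad;
}

// -------------------------------------------------------------- joint sweep
// Exhaustive classification of an (roll, yaw, pitch) grid for one joint.
// The anterior (cranial) vertebra rotates about `cor`; rotations compose
// intrinsically roll (joint x) -> yaw (rotated y) -> pitch (rotated z),
// i.e. R = A Rx(roll) Ry(yaw) Rz(pitch) A^T with A = [x y z] axis columns.
// Flags per pose: collision_free, articulated_left, articulated_right.
// [[Rcpp::export]]
IntegerMatrix cpp_sweep_joint(NumericMatrix Vant, IntegerMatrix Fant, NumericMatrix Vpost,
                              IntegerMatrix Fpost, NumericMatrix VgL, IntegerMatrix FgL,
                              NumericMatrix VgR, IntegerMatrix FgR, NumericVector cor,
                              NumericMatrix axes, NumericMatrix angles) {
  Mesh ant = as_mesh(Vant, Fant);
  Mesh post = as_mesh(Vpost, Fpost);
  Mesh gL = as_mesh(VgL, FgL);
  Mesh gR = as_mesh(VgR, FgR);
  BVH bpost, bL, bR;
  bpost.build(post);
  bL.build(gL);
  bR.build(gR);

  const int n = angles.nrow();
  IntegerMatrix out(n, 3);
  Mesh moved = ant;
  const double d2r = M_PI / 180.0;
  double A[3][3];
  for (int r = 0; r < 3; ++r)
    for (int c = 0; c < 3; ++c) A[r][c] = axes(r, c);
  V3 cc = v3(cor[0], cor[1], cor[2]);

  for (int i = 0; i < n; ++i) {
    double ro = angles(i, 0) * d2r, ya = angles(i, 1) * d2r, pi = angles(i, 2) * d2r;
    double cr = std::cos(ro), sr = std::sin(ro);
    double cy = std::cos(ya), sy = std::sin(ya);
    double cp = std::cos(pi), sp = std::sin(pi);
    // Rx(ro) Ry(ya) Rz(pi)
    double R0[3][3] = {{cy * cp, -cy * sp, sy},
                       {sr * sy * cp + cr * sp, -sr * sy * sp + cr * cp, -sr * cy},
                       {-cr * sy * cp + sr * sp, cr * sy * sp + sr * cp, cr * cy}};
    // R = A R0 A^T
    double AR[3][3], R[3][3];
    for (int r = 0; r < 3; ++r)
      for (int c = 0; c < 3; ++c)
        AR[r][c] = A[r][0] * R0[0][c] + A[r][1] * R0[1][c] + A[r][2] * R0[2][c];
    for (int r = 0; r < 3; ++r)
      for (int c = 0; c < 3; ++c)
        R[r][c] = AR[r][0] * A[c][0] + AR[r][1] * A[c][1] + AR[r][2] * A[c][2];

    for (size_t k = 0; k < ant.v.size(); ++k) {
      V3 d = sub(ant.v[k], cc);
      moved.v[k] = v3(cc.x + R[0][0] * d.x + R[0][1] * d.y + R[0][2] * d.z,
                      cc.y + R[1][0] * d.x + R[1][1] * d.y + R[1][2] * d.z,
                      cc.z + R[2][0] * d.x + R[2][1] * d.y + R[2][2] * d.z);
    }
    bool collide = meshes_intersect_bvh(moved, post, bpost);
    bool artL = meshes_intersect_bvh(moved, gL, bL);
    bool artR = meshes_intersect_bvh(moved, gR, bR);
    out(i, 0) = collide ? 0 : 1;
    out(i, 1) = artL ? 1 : 0;
    out(i, 2) = artR ? 1 : 0;
  }
  return out;
}

// per-point minimum distance to a triangle mesh
// [[Rcpp::export]]
NumericVector cpp_points_mesh_distance(NumericMatrix P, NumericMatrix V, IntegerMatrix F) {
  Mesh m = as_mesh(V, F);
  NumericVector out(P.nrow());
  for (int i = 0; i < P.nrow(); ++i) {
    V3 p = v3(P(i, 0), P(i, 1), P(i, 2));
    double best = 1e300;
    for (size_t t = 0; t < m.f.size(); ++t) {
      best = std::min(best, point_tri_dist2(p, m.v[m.f[t][0]], m.v[m.f[t][1]],
                                            m.v[m.f[t][2]]));
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
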