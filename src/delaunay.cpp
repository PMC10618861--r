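// Incremental (Bowyer-Watson) 3-D Delaunay tetrahedralisation.
// Input points are expected in general position; the R wrapper applies a
// deterministic sub-micro jitter to grid-like data before calling in here.
// Returns tetrahedra (1-based vertex indices), circumradii and volumes --
// everything the alpha-complex volume and critical-alpha search need.
#include <Rcpp.h>
#include <vector>
#include <array>
#include <map>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

namespace {

struct P3 {
  double x, y, z;
};

inline double det3(double a, double b, double c, double d, double e, double f, double g,
                   double h, double i) {
  return a * (e * i - f * h) - b * (d * i - f * g) + c * (d * h - e * g);
}

inline double orient(const P3 &a, const P3 &b, const P3 &c, const P3 &d) {
  return det3(b.x - a.x, b.y - a.y, b.z - a.z, c.x - a.x, c.y - a.y, c.z - a.z, d.x - a.x,
              d.y - a.y, d.z - a.z);
}

struct Tet {
  int v[4];
  int nb[4];  // neighbour opposite v[i]; -1 = none
  bool alive;
  double cc[3];
  double r2;
};

struct Triangulation {
  std::vector<P3> pts;
  std::vector<Tet> tets;
  int last_alive = 0;

  bool circum(Tet &t) {
    const P3 &a = pts[t.v[0]], &b = pts[t.v[1]], &c = pts[t.v[2]], &d = pts[t.v[3]];
    double ax = b.x - a.x, ay = b.y - a.y, az = b.z - a.z;
    double bx = c.x - a.x, by = c.y - a.y, bz = c.z - a.z;
    double cx = d.x - a.x, cy = d.y - a.y, cz = d.z - a.z;
    double D = 2.0 * det3(ax, ay, az, bx, by, bz, cx, cy, cz);
    if (std::fabs(D) < 1e-300) return false;
    double ra = ax * ax + ay * ay + az * az;
    double rb = bx * bx + by * by + bz * bz;
    double rc = cx * cx + cy * cy + cz * cz;
    double ux = det3(ra, ay, az, rb, by, bz, rc, cy, cz) / D;
    double uy = det3(ax, ra, az, bx, rb, bz, cx, rc, cz) / D;
    double uz = det3(ax, ay, ra, bx, by, rb, cx, cy, rc) / D;
    t.cc[0] = a.x + ux;
    t.cc[1] = a.y + uy;
    t.cc[2] = a.z + uz;
    t.r2 = ux * ux + uy * uy + uz * uz;
    return true;
  }

  inline bool in_sphere(const Tet &t, const P3 &p) const {
    double dx = p.x - t.cc[0], dy = p.y - t.cc[1], dz = p.z - t.cc[2];
    return dx * dx + dy * dy + dz * dz < t.r2;
  }

  int make_tet(int a, int b, int c, int d) {
    Tet t;
    t.v[0] = a; t.v[1] = b; t.v[2] = c; t.v[3] = d;
    if (orient(pts[a], pts[b], pts[c], pts[d]) < 0) std::swap(t.v[2], t.v[3]);
    t.nb[0] = t.nb[1] = t.nb[2] = t.nb[3] = -1;
    t.alive = true;
    if (!circum(t)) {
      // numerically flat: huge circumsphere so it is always re-triangulated
      t.cc[0] = t.cc[1] = t.cc[2] = 0.0;
      t.r2 = 1e300;
    }
    tets.push_back(t);
    return (int)tets.size() - 1;
  }

  // locate a tetrahedron whose circumsphere contains p (walk, then scan)
  int locate(const P3 &p) {
    int cur = last_alive;
    if (cur >= (int)tets.size() || !tets[cur].alive) {
      cur = -1;
      for (int i = (int)tets.size() - 1; i >= 0; --i)
        if (tets[i].alive) { cur = i; break; }
    }
    int guard = 4 * (int)tets.size() + 64;
    while (guard-- > 0) {
      const Tet &t = tets[cur];
      int exit = -1;
      for (int f = 0; f < 4; ++f) {
        // face opposite v[f]; orientation chosen so v[f] is on positive side
        int a = t.v[(f + 1) % 4], b = t.v[(f + 2) % 4], c = t.v[(f + 3) % 4];
        double o_in = orient(pts[a], pts[b], pts[c], pts[t.v[f]]);
        double o_p = orient(pts[a], pts[b], pts[c], p);
        if (o_in * o_p < 0) { exit = f; break; }
      }
      if (exit < 0) return cur;  // inside
      int nxt = t.nb[exit];
      if (nxt < 0 || !tets[nxt].alive) break;
      cur = nxt;
    }
    // fallback: linear scan for any alive tet whose circumsphere holds p
    for (int i = (int)tets.size() - 1; i >= 0; --i)
      if (tets[i].alive && in_sphere(tets[i], p)) return i;
    return -1;
  }

  void insert(int ip) {
    const P3 &p = pts[ip];
    int seed = locate(p);
    if (seed < 0) return;  // duplicate / unreachable point: skip
    // cavity = connected bad tets (circumsphere contains p)
    std::vector<int> cavity;
    std::vector<int> stack{seed};
    std::vector<char> mark(tets.size(), 0);
    if (!in_sphere(tets[seed], p)) {
      // containing tet must be bad by Delaunay property; if the walk landed
      // on a boundary tet treat it as the cavity seed anyway
      mark[seed] = 1;
      cavity.push_back(seed);
      stack.pop_back();
    } else {
      mark[seed] = 1;
    }
    while (!stack.empty()) {
      int t = stack.back();
      stack.pop_back();
      cavity.push_back(t);
      for (int f = 0; f < 4; ++f) {
        int nb = tets[t].nb[f];
        if (nb >= 0 && tets[nb].alive && !mark[nb] && in_sphere(tets[nb], p)) {
          mark[nb] = 1;
          stack.push_back(nb);
        }
      }
    }
    // boundary faces of the cavity
    struct BFace {
      int a, b, c;   // oriented so that p sees it from inside
      int outside;   // tet index beyond the face, -1 if hull
    };
    std::vector<BFace> bfaces;
    for (int t : cavity) {
      for (int f = 0; f < 4; ++f) {
        int nb = tets[t].nb[f];
        if (nb >= 0 && mark[nb]) continue;
        int a = tets[t].v[(f + 1) % 4], b = tets[t].v[(f + 2) % 4],
            c = tets[t].v[(f + 3) % 4];
        bfaces.push_back({a, b, c, nb});
      }
    }
    for (int t : cavity) tets[t].alive = false;

    // retriangulate: connect p to each boundary face
    std::map<std::pair<int, int>, std::pair<int, int>> edge2slot;  // edge -> (tet, slot)
    std::vector<int> created;
    for (const BFace &bf : bfaces) {
      int nt = make_tet(ip, bf.a, bf.b, bf.c);
      created.push_back(nt);
      // slot of face (a,b,c) = the one opposite ip
      int slot_abc = -1;
      for (int f = 0; f < 4; ++f)
        if (tets[nt].v[f] == ip) { slot_abc = f; break; }
      tets[nt].nb[slot_abc] = bf.outside;
      if (bf.outside >= 0) {
        // fix back-pointer on the outside tet
        Tet &o = tets[bf.outside];
        for (int f = 0; f < 4; ++f) {
          int oa = o.v[(f + 1) % 4], ob = o.v[(f + 2) % 4], oc = o.v[(f + 3) % 4];
          int match = 0;
          for (int x : {oa, ob, oc})
            if (x == bf.a || x == bf.b || x == bf.c) ++match;
          if (match == 3) { o.nb[f] = nt; break; }
        }
      }
      // wire internal faces (contain ip and one boundary edge)
      int tri[3] = {bf.a, bf.b, bf.c};
      for (int e = 0; e < 3; ++e) {
        int x = tri[e], y = tri[(e + 1) % 3];
        std::pair<int, int> key(std::min(x, y), std::max(x, y));
        // slot opposite the third boundary vertex
        int third = tri[(e + 2) % 3];
        int slot = -1;
        for (int f = 0; f < 4; ++f)
          if (tets[nt].v[f] == third) { slot = f; break; }
        auto it = edge2slot.find(key);
        if (it == edge2slot.end()) {
          edge2slot[key] = {nt, slot};
        } else {
          tets[nt].nb[slot] = it->second.first;
          tets[it->second.first].nb[it->second.second] = nt;
          edge2slot.erase(it);
        }
      }
    }
    if (!created.empty()) last_alive = created.back();
  }
};

}  // namespace

// [[Rcpp::export]]
List cpp_delaunay3(NumericMatrix P) {
  int n = P.nrow();
  if (n < 4) stop("need at least 4 points");
  Triangulation T;
  T.pts.resize(n + 4);
  double lo[3] = {1e300, 1e300, 1e300}, hi[3] = {-1e300, -1e300, -1e300};
  for (int i = 0; i < n; ++i) {
    T.pts[i] = {P(i, 0), P(i, 1), P(i, 2)};
    for (int k = 0; k < 3; ++k) {
      lo[k] = std::min(lo[k], P(i, k));
      hi[k] = std::max(hi[k], P(i, k));
    }
  }
  double cx = 0.5 * (lo[0] + hi[0]), cy = 0.5 * (lo[1] + hi[1]), cz = 0.5 * (lo[2] + hi[2]);
  double span = std::max({hi[0] - lo[0], hi[1] - lo[1], hi[2] - lo[2], 1.0});
  double s = 50.0 * span;
  // big enclosing tetrahedron
  T.pts[n + 0] = {cx - 2.0 * s, cy - s, cz - s};
  T.pts[n + 1] = {cx + 2.0 * s, cy - s, cz - s};
  T.pts[n + 2] = {cx, cy + 2.0 * s, cz - s};
  T.pts[n + 3] = {cx, cy, cz + 2.0 * s};
  T.make_tet(n, n + 1, n + 2, n + 3);

  for (int i = 0; i < n; ++i) T.insert(i);

  // harvest tets with only real vertices
  std::vector<std::array<int, 4>> keep;
  std::vector<double> radii, vols;
  for (const Tet &t : T.tets) {
    if (!t.alive) continue;
    if (t.v[0] >= n || t.v[1] >= n || t.v[2] >= n || t.v[3] >= n) continue;
    double vol = orient(T.pts[t.v[0]], T.pts[t.v[1]], T.pts[t.v[2]], T.pts[t.v[3]]) / 6.0;
    keep.push_back({t.v[0], t.v[1], t.v[2], t.v[3]});
    radii.push_back(std::sqrt(t.r2));
    vols.push_back(std::fabs(vol));
  }
  IntegerMatrix tets(keep.size(), 4);
  for (size_t i = 0; i < keep.size(); ++i)
    for (int j = 0; j < 4; ++j) tets(i, j) = keep[i][j] + 1;
  return List::create(Named("tets") = tets, Named("circumradius") = wrap(radii),
                      Named("volume") = wrap(vols));
}
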