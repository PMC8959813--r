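#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <unordered_map>
using namespace Rcpp;

// Quickhull in 3D. Returns hull volume, total facet area and the indices of
// the hull vertices. Written against exact analytic solids in the test suite
// (cube, tetrahedron, ellipsoid point sets) because no qhull binding is
// available in the dependency stack.

namespace {

struct Face {
  int v[3];          // vertex indices, outward CCW
  double n[3];       // outward unit-ish normal (not normalised)
  double off;        // plane offset: n . x = off
  int nb[3];         // neighbour across edge (v0,v1), (v1,v2), (v2,v0)
  std::vector<int> outside;
  int far_idx = -1;
  double far_d = 0.0;
  bool alive = true;
};

inline void sub3(const double* a, const double* b, double* out) {
  out[0] = a[0] - b[0]; out[1] = a[1] - b[1]; out[2] = a[2] - b[2];
}
inline void cross3(const double* a, const double* b, double* out) {
  out[0] = a[1] * b[2] - a[2] * b[1];
  out[1] = a[2] * b[0] - a[0] * b[2];
  out[2] = a[0] * b[1] - a[1] * b[0];
}
inline double dot3(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}

class Hull {
public:
  const NumericMatrix& P;
  double eps;
  double interior[3];
  std::vector<Face> faces;
  std::vector<int> stack;

  Hull(const NumericMatrix& P_) : P(P_) {}

  void pt(int i, double* out) const {
    out[0] = P(i, 0); out[1] = P(i, 1); out[2] = P(i, 2);
  }

  double dist(const Face& f, int i) const {
    double p[3]; pt(i, p);
    return dot3(f.n, p) - f.off;
  }

  // plane through the face's vertices; optionally re-orient away from the
  // interior point. Only the initial simplex is re-oriented — cone faces over
  // a horizon are already outward by construction, and re-flipping a
  // numerically degenerate sliver would corrupt the directed-edge manifold.
  void set_plane(Face& f, bool allow_flip) {
    double a[3], b[3], c[3], ab[3], ac[3];
    pt(f.v[0], a); pt(f.v[1], b); pt(f.v[2], c);
    sub3(b, a, ab); sub3(c, a, ac);
    cross3(ab, ac, f.n);
    f.off = dot3(f.n, a);
    if (allow_flip && dot3(f.n, interior) - f.off > 0) {
      std::swap(f.v[1], f.v[2]);
      f.n[0] = -f.n[0]; f.n[1] = -f.n[1]; f.n[2] = -f.n[2];
      f.off = -f.off;
      std::swap(f.nb[0], f.nb[2]);
    }
  }

  void build(double tol_scale) {
    const int n = P.nrow();
    if (n < 4) stop("need at least 4 points for a 3D hull");

    // scale for epsilon
    double lo[3], hi[3];
    for (int k = 0; k < 3; ++k) { lo[k] = R_PosInf; hi[k] = R_NegInf; }
    for (int i = 0; i < n; ++i)
      for (int k = 0; k < 3; ++k) {
        double v = P(i, k);
        if (v < lo[k]) lo[k] = v;
        if (v > hi[k]) hi[k] = v;
      }
    double scale = 0.0;
    for (int k = 0; k < 3; ++k)
      scale = std::max(scale, std::max(std::fabs(lo[k]), std::fabs(hi[k])));
    if (scale == 0.0) scale = 1.0;
    eps = tol_scale * scale;

    // initial simplex: extremes along x, then farthest from line, then plane
    int i0 = 0, i1 = 0;
    for (int i = 1; i < n; ++i) {
      if (P(i, 0) < P(i0, 0)) i0 = i;
      if (P(i, 0) > P(i1, 0)) i1 = i;
    }
    if (i0 == i1) { i1 = (i0 == 0) ? 1 : 0; }
    double p0[3], p1[3]; pt(i0, p0); pt(i1, p1);
    double d01[3]; sub3(p1, p0, d01);
    double len01 = std::sqrt(dot3(d01, d01));
    if (len01 <= eps) stop("degenerate input: points nearly coincident");

    int i2 = -1; double best = -1.0;
    for (int i = 0; i < n; ++i) {
      double p[3], v[3], c[3]; pt(i, p); sub3(p, p0, v); cross3(d01, v, c);
      double d = std::sqrt(dot3(c, c)) / len01;
      if (d > best) { best = d; i2 = i; }
    }
    if (best <= eps) stop("degenerate input: points are collinear");

    double p2[3]; pt(i2, p2);
    double d02[3], nrm[3]; sub3(p2, p0, d02); cross3(d01, d02, nrm);
    double nlen = std::sqrt(dot3(nrm, nrm));
    int i3 = -1; best = -1.0;
    for (int i = 0; i < n; ++i) {
      double p[3], v[3]; pt(i, p); sub3(p, p0, v);
      double d = std::fabs(dot3(nrm, v)) / nlen;
      if (d > best) { best = d; i3 = i; }
    }
    if (best <= eps) stop("degenerate input: points are coplanar");

    double p3[3]; pt(i3, p3);
    for (int k = 0; k < 3; ++k)
      interior[k] = (p0[k] + p1[k] + p2[k] + p3[k]) / 4.0;

    int tet[4] = {i0, i1, i2, i3};
    int fv[4][3] = {{0, 1, 2}, {0, 1, 3}, {0, 2, 3}, {1, 2, 3}};
    faces.resize(4);
    for (int f = 0; f < 4; ++f) {
      for (int k = 0; k < 3; ++k) faces[f].v[k] = tet[fv[f][k]];
      faces[f].nb[0] = faces[f].nb[1] = faces[f].nb[2] = -1;
      set_plane(faces[f], true);
    }
    // brute-force neighbour wiring among the 4 faces
    for (int f = 0; f < 4; ++f)
      for (int e = 0; e < 3; ++e) {
        int a = faces[f].v[e], b = faces[f].v[(e + 1) % 3];
        for (int g = 0; g < 4; ++g) {
          if (g == f) continue;
          for (int e2 = 0; e2 < 3; ++e2) {
            int c = faces[g].v[e2], d2 = faces[g].v[(e2 + 1) % 3];
            if (a == d2 && b == c) faces[f].nb[e] = g;
          }
        }
      }

    // initial outside sets
    for (int i = 0; i < n; ++i) {
      if (i == i0 || i == i1 || i == i2 || i == i3) continue;
      assign_point(i, 0, 4);
    }
    for (int f = 0; f < 4; ++f)
      if (!faces[f].outside.empty()) stack.push_back(f);

    process();
  }

  // assign point i to the first face in [from, to) it lies strictly above
  void assign_point(int i, int from, int to) {
    for (int f = from; f < to; ++f) {
      if (!faces[f].alive) continue;
      double d = dist(faces[f], i);
      if (d > eps) {
        faces[f].outside.push_back(i);
        if (d > faces[f].far_d) { faces[f].far_d = d; faces[f].far_idx = i; }
        return;
      }
    }
  }

  void process() {
    std::vector<int> visible, horizon_face, horizon_edge;
    std::vector<char> mark(faces.size(), 0);
    while (!stack.empty()) {
      int fi = stack.back(); stack.pop_back();
      if (!faces[fi].alive || faces[fi].outside.empty()) continue;
      int p = faces[fi].far_idx;

      // BFS for faces visible from p
      visible.clear(); horizon_face.clear(); horizon_edge.clear();
      if (mark.size() < faces.size()) mark.resize(faces.size(), 0);
      std::vector<int> bfs; bfs.push_back(fi); mark[fi] = 1;
      for (size_t q = 0; q < bfs.size(); ++q) {
        int f = bfs[q];
        visible.push_back(f);
        for (int e = 0; e < 3; ++e) {
          int g = faces[f].nb[e];
          if (g < 0) stop("internal hull error: open boundary");
          if (mark[g]) continue;
          if (dist(faces[g], p) > eps) {
            mark[g] = 1; bfs.push_back(g);
          } else {
            horizon_face.push_back(f);
            horizon_edge.push_back(e);
          }
        }
      }
      for (int f : bfs) mark[f] = 0;

      // build the cone of new faces over the horizon
      std::vector<int> newf;
      for (size_t h = 0; h < horizon_face.size(); ++h) {
        int f = horizon_face[h], e = horizon_edge[h];
        int a = faces[f].v[e], b = faces[f].v[(e + 1) % 3];
        int outer = faces[f].nb[e];
        Face nf;
        nf.v[0] = a; nf.v[1] = b; nf.v[2] = p;
        nf.nb[0] = outer; nf.nb[1] = -1; nf.nb[2] = -1;
        set_plane(nf, false);
        int id = (int)faces.size();
        faces.push_back(nf);
        mark.push_back(0);
        newf.push_back(id);
        // rewire outer neighbour to point at the new face
        Face& of = faces[outer];
        for (int e2 = 0; e2 < 3; ++e2) {
          int c = of.v[e2], d2 = of.v[(e2 + 1) % 3];
          if (c == b && d2 == a) of.nb[e2] = id;
        }
      }
      // wire new faces to each other by matching directed edges: the
      // neighbour across (u,v) carries (v,u). This stays correct even when
      // the eps-visibility horizon pinches at a vertex.
      {
        std::unordered_map<long long, int> edge_owner;
        const long long N = (long long)P.nrow() + 1;
        for (int id : newf) {
          Face& f = faces[id];
          for (int e = 0; e < 3; ++e) {
            if (f.nb[e] >= 0) continue;
            long long key = (long long)f.v[e] * N + f.v[(e + 1) % 3];
            edge_owner[key] = id;
          }
        }
        for (int id : newf) {
          Face& f = faces[id];
          for (int e = 0; e < 3; ++e) {
            if (f.nb[e] >= 0) continue;
            long long rev = (long long)f.v[(e + 1) % 3] * N + f.v[e];
            auto it = edge_owner.find(rev);
            if (it == edge_owner.end())
              stop("internal hull error: horizon wiring failed");
            f.nb[e] = it->second;
          }
        }
      }

      // retire visible faces, redistribute their outside points
      for (int f : visible) faces[f].alive = false;
      for (int f : visible) {
        for (int i : faces[f].outside) {
          if (i == p) continue;
          for (int id : newf) {
            double d = dist(faces[id], i);
            if (d > eps) {
              faces[id].outside.push_back(i);
              if (d > faces[id].far_d) {
                faces[id].far_d = d; faces[id].far_idx = i;
              }
              break;
            }
          }
        }
        faces[f].outside.clear();
        faces[f].outside.shrink_to_fit();
      }
      for (int id : newf)
        if (!faces[id].outside.empty()) stack.push_back(id);
    }
  }
};

} // namespace

// [[Rcpp::export]]
List convex_hull_3d_cpp(NumericMatrix pts, double tol = 1e-10) {
  Hull h(pts);
  h.build(tol);

  double vol = 0.0, area = 0.0;
  std::vector<char> is_vert(pts.nrow(), 0);
  int nfaces = 0;
  for (const Face& f : h.faces) {
    if (!f.alive) continue;
    ++nfaces;
    double a[3], b[3], c[3]; h.pt(f.v[0], a); h.pt(f.v[1], b); h.pt(f.v[2], c);
    double ab[3], ac[3], cr[3];
    sub3(b, a, ab); sub3(c, a, ac); cross3(ab, ac, cr);
    area += 0.5 * std::sqrt(dot3(cr, cr));
    double ao[3]; sub3(a, h.interior, ao);
    double bo[3]; sub3(b, h.interior, bo);
    double co[3]; sub3(c, h.interior, co);
    double cr2[3]; cross3(bo, co, cr2);
    vol += dot3(ao, cr2) / 6.0;
    for (int k = 0; k < 3; ++k) is_vert[f.v[k]] = 1;
  }
  IntegerVector verts;
  {
    std::vector<int> v;
    for (int i = 0; i < (int)is_vert.size(); ++i)
      if (is_vert[i]) v.push_back(i + 1); // 1-based for R
    verts = wrap(v);
  }
  return List::create(_["volume"] = vol, _["area"] = area,
                      _["n_faces"] = nfaces, _["vertices"] = verts);
}
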