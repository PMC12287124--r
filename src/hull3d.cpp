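#include <Rcpp.h>
#include <vector>
#include <array>
#include <map>
#include <cmath>
using namespace Rcpp;

// Incremental 3D convex hull, volume only. Faces are kept with consistent
// outward orientation so the divergence-theorem volume needs no interior
// reference point. Points within eps of a face plane are treated as
// non-visible, which keeps near-coplanar inputs stable at the cost of a
// volume error well below the eps * surface-area scale.

namespace {

struct Vec3 {
  double x, y, z;
};

inline Vec3 sub(const Vec3& a, const Vec3& b) {
  return Vec3{a.x - b.x, a.y - b.y, a.z - b.z};
}
inline Vec3 cross(const Vec3& a, const Vec3& b) {
  return Vec3{a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z,
              a.x * b.y - a.y * b.x};
}
inline double dot(const Vec3& a, const Vec3& b) {
  return a.x * b.x + a.y * b.y + a.z * b.z;
}
inline double norm(const Vec3& a) { return std::sqrt(dot(a, a)); }

struct Face {
  int a, b, c;     // vertex indices, CCW seen from outside
  Vec3 n;          // outward normal (not normalized)
  double offset;   // dot(n, vertex a)
  bool alive;
};

inline Face make_face(int a, int b, int c, const std::vector<Vec3>& P) {
  Vec3 n = cross(sub(P[b], P[a]), sub(P[c], P[a]));
  return Face{a, b, c, n, dot(n, P[a]), true};
}

// signed distance of p above face plane, scaled by |n|
inline double above(const Face& f, const Vec3& p) {
  return dot(f.n, p) - f.offset;
}

}  // namespace

// [[Rcpp::export(name = ".hull3d_volume")]]
double hull3d_volume(NumericMatrix pts) {
  const int n = pts.nrow();
  if (n < 4) return 0.0;
  std::vector<Vec3> P(n);
  double diam = 0.0;
  for (int i = 0; i < n; ++i) P[i] = Vec3{pts(i, 0), pts(i, 1), pts(i, 2)};

  // bounding-box diameter for epsilon scaling
  Vec3 lo = P[0], hi = P[0];
  for (const Vec3& p : P) {
    lo.x = std::min(lo.x, p.x); hi.x = std::max(hi.x, p.x);
    lo.y = std::min(lo.y, p.y); hi.y = std::max(hi.y, p.y);
    lo.z = std::min(lo.z, p.z); hi.z = std::max(hi.z, p.z);
  }
  diam = norm(sub(hi, lo));
  if (diam <= 0.0) return 0.0;
  const double eps = 1e-12 * diam;

  // initial simplex: extreme in x, farthest point, farthest from line,
  // farthest from plane
  int i0 = 0;
  for (int i = 1; i < n; ++i) if (P[i].x < P[i0].x) i0 = i;
  int i1 = -1; double best = eps;
  for (int i = 0; i < n; ++i) {
    double d = norm(sub(P[i], P[i0]));
    if (d > best) { best = d; i1 = i; }
  }
  if (i1 < 0) return 0.0;
  Vec3 dir = sub(P[i1], P[i0]);
  int i2 = -1; best = eps * diam;
  for (int i = 0; i < n; ++i) {
    double d = norm(cross(dir, sub(P[i], P[i0])));
    if (d > best) { best = d; i2 = i; }
  }
  if (i2 < 0) return 0.0;  // collinear
  Vec3 nrm = cross(dir, sub(P[i2], P[i0]));
  int i3 = -1; best = eps * norm(nrm);
  for (int i = 0; i < n; ++i) {
    double d = std::fabs(dot(nrm, sub(P[i], P[i0])));
    if (d > best) { best = d; i3 = i; }
  }
  if (i3 < 0) return 0.0;  // coplanar

  std::vector<Face> faces;
  faces.reserve(256);
  {
    // orient each face away from the remaining simplex vertex
    const int v[4] = {i0, i1, i2, i3};
    const int tri[4][3] = {{0, 1, 2}, {0, 1, 3}, {0, 2, 3}, {1, 2, 3}};
    const int opp[4] = {3, 2, 1, 0};
    for (int f = 0; f < 4; ++f) {
      Face fc = make_face(v[tri[f][0]], v[tri[f][1]], v[tri[f][2]], P);
      if (above(fc, P[v[opp[f]]]) > 0)
        fc = make_face(v[tri[f][0]], v[tri[f][2]], v[tri[f][1]], P);
      faces.push_back(fc);
    }
  }

  std::vector<int> visible;
  for (int i = 0; i < n; ++i) {
    if (i == i0 || i == i1 || i == i2 || i == i3) continue;
    visible.clear();
    for (int f = 0; f < (int)faces.size(); ++f) {
      if (!faces[f].alive) continue;
      // visibility tolerance relative to face scale
      if (above(faces[f], P[i]) > eps * (norm(faces[f].n) + 1.0))
        visible.push_back(f);
    }
    if (visible.empty()) continue;
    // horizon = directed edges of visible faces whose reverse edge is not in
    // a visible face
    std::map<std::pair<int, int>, int> edge_count;
    for (int f : visible) {
      const Face& fc = faces[f];
      const int e[3][2] = {{fc.a, fc.b}, {fc.b, fc.c}, {fc.c, fc.a}};
      for (auto& ed : e) {
        auto rev = std::make_pair(ed[1], ed[0]);
        auto it = edge_count.find(rev);
        if (it != edge_count.end())
          edge_count.erase(it);
        else
          edge_count[std::make_pair(ed[0], ed[1])] = 1;
      }
    }
    for (int f : visible) faces[f].alive = false;
    for (auto& kv : edge_count)
      faces.push_back(make_face(kv.first.first, kv.first.second, i, P));
  }

  // divergence theorem: V = (1/6) * sum over faces of dot(a, b x c)
  double vol6 = 0.0;
  for (const Face& f : faces) {
    if (!f.alive) continue;
    vol6 += dot(P[f.a], cross(P[f.b], P[f.c]));
  }
  return std::fabs(vol6) / 6.0;
}
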