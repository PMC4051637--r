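// Voronoi cell construction by incremental half-space clipping.
//
// The cell of a point p is the intersection of the bisector half-spaces
// against all other points. Neighbours are supplied sorted by increasing
// distance; once the next neighbour is farther than twice the current
// maximum vertex distance it can no longer cut the cell, so the loop stops.
// This makes the construction exact while touching only nearby points.

#include <Rcpp.h>
#include <vector>
#include <array>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

static const double EPS = 1e-9;

// ---------------------------------------------------------------- 2D ----

// [[Rcpp::export]]
List voronoi_cell_2d(NumericVector p, NumericMatrix nbrs, NumericVector dist,
                     double boxHalf) {
  std::vector<std::array<double, 2>> poly = {
    {p[0] - boxHalf, p[1] - boxHalf}, {p[0] + boxHalf, p[1] - boxHalf},
    {p[0] + boxHalf, p[1] + boxHalf}, {p[0] - boxHalf, p[1] + boxHalf}};
  int n = nbrs.nrow();
  double rmax = 2.0 * boxHalf;
  bool exhausted = true;
  for (int j = 0; j < n; ++j) {
    if (dist[j] > 2.0 * rmax + EPS) { exhausted = false; break; }
    double ux = nbrs(j, 0) - p[0], uy = nbrs(j, 1) - p[1];
    double b = ux * (p[0] + nbrs(j, 0)) * 0.5 + uy * (p[1] + nbrs(j, 1)) * 0.5;
    std::vector<std::array<double, 2>> out;
    out.reserve(poly.size() + 2);
    size_t m = poly.size();
    bool cut = false;
    for (size_t i = 0; i < m; ++i) {
      const std::array<double, 2> &v1 = poly[i];
      const std::array<double, 2> &v2 = poly[(i + 1) % m];
      double f1 = ux * v1[0] + uy * v1[1] - b;
      double f2 = ux * v2[0] + uy * v2[1] - b;
      bool in1 = f1 <= EPS, in2 = f2 <= EPS;
      if (in1) out.push_back(v1);
      if (in1 != in2 && std::fabs(f1 - f2) > 1e-300) {
        double t = f1 / (f1 - f2);
        t = std::max(0.0, std::min(1.0, t));
        out.push_back({v1[0] + t * (v2[0] - v1[0]),
                       v1[1] + t * (v2[1] - v1[1])});
        cut = true;
      }
      if (!in1) cut = true;
    }
    if (cut) poly = out;
    rmax = 0.0;
    for (auto &v : poly) {
      double dx = v[0] - p[0], dy = v[1] - p[1];
      rmax = std::max(rmax, std::sqrt(dx * dx + dy * dy));
    }
  }
  // Deduplicate vertices.
  std::vector<std::array<double, 2>> verts;
  for (auto &v : poly) {
    bool dup = false;
    for (auto &w : verts)
      if (std::fabs(v[0] - w[0]) <= 1e-9 && std::fabs(v[1] - w[1]) <= 1e-9) {
        dup = true; break;
      }
    if (!dup) verts.push_back(v);
  }
  NumericMatrix V(verts.size(), 2);
  bool touches = false;
  for (size_t i = 0; i < verts.size(); ++i) {
    V(i, 0) = verts[i][0]; V(i, 1) = verts[i][1];
    if (std::fabs(verts[i][0] - p[0]) >= boxHalf - 1e-7 ||
        std::fabs(verts[i][1] - p[1]) >= boxHalf - 1e-7) touches = true;
  }
  return List::create(_["vertices"] = V, _["touchesBox"] = touches,
                      _["exhausted"] = exhausted, _["rmax"] = rmax);
}

// ---------------------------------------------------------------- 3D ----

typedef std::array<double, 3> P3;
typedef std::vector<P3> Face;

static inline bool samePoint(const P3 &a, const P3 &b) {
  return std::fabs(a[0] - b[0]) <= 1e-9 && std::fabs(a[1] - b[1]) <= 1e-9 &&
         std::fabs(a[2] - b[2]) <= 1e-9;
}

// Clip the polyhedron (list of convex face polygons) by u.x <= b.
static void clipPoly3(std::vector<Face> &faces, const P3 &u, double b) {
  std::vector<Face> out;
  Face cap;
  bool cut = false;
  for (Face &f : faces) {
    Face nf;
    size_t m = f.size();
    for (size_t i = 0; i < m; ++i) {
      const P3 &v1 = f[i];
      const P3 &v2 = f[(i + 1) % m];
      double f1 = u[0] * v1[0] + u[1] * v1[1] + u[2] * v1[2] - b;
      double f2 = u[0] * v2[0] + u[1] * v2[1] + u[2] * v2[2] - b;
      bool in1 = f1 <= EPS, in2 = f2 <= EPS;
      if (in1) {
        nf.push_back(v1);
        if (f1 >= -EPS) cap.push_back(v1);
      } else {
        cut = true;
      }
      if (in1 != in2 && std::fabs(f1 - f2) > 1e-300) {
        double t = f1 / (f1 - f2);
        if (t > 0.0 && t < 1.0) {
          P3 w = {v1[0] + t * (v2[0] - v1[0]), v1[1] + t * (v2[1] - v1[1]),
                  v1[2] + t * (v2[2] - v1[2])};
          nf.push_back(w);
          cap.push_back(w);
        }
      }
    }
    if (nf.size() >= 3) out.push_back(nf);
  }
  if (!cut) return;
  // Build the new cap face: deduplicate and order around its centroid.
  Face cu;
  for (P3 &v : cap) {
    bool dup = false;
    for (P3 &w : cu) if (samePoint(v, w)) { dup = true; break; }
    if (!dup) cu.push_back(v);
  }
  if (cu.size() >= 3) {
    P3 c = {0, 0, 0};
    for (P3 &v : cu) { c[0] += v[0]; c[1] += v[1]; c[2] += v[2]; }
    for (int a = 0; a < 3; ++a) c[a] /= cu.size();
    // Orthonormal basis of the cap plane.
    double un = std::sqrt(u[0] * u[0] + u[1] * u[1] + u[2] * u[2]);
    P3 nu = {u[0] / un, u[1] / un, u[2] / un};
    P3 ref = std::fabs(nu[0]) < 0.9 ? P3{1, 0, 0} : P3{0, 1, 0};
    P3 e1 = {nu[1] * ref[2] - nu[2] * ref[1], nu[2] * ref[0] - nu[0] * ref[2],
             nu[0] * ref[1] - nu[1] * ref[0]};
    double e1n = std::sqrt(e1[0] * e1[0] + e1[1] * e1[1] + e1[2] * e1[2]);
    for (int a = 0; a < 3; ++a) e1[a] /= e1n;
    P3 e2 = {nu[1] * e1[2] - nu[2] * e1[1], nu[2] * e1[0] - nu[0] * e1[2],
             nu[0] * e1[1] - nu[1] * e1[0]};
    std::vector<std::pair<double, size_t>> ang(cu.size());
    for (size_t i = 0; i < cu.size(); ++i) {
      P3 dv = {cu[i][0] - c[0], cu[i][1] - c[1], cu[i][2] - c[2]};
      double x = dv[0] * e1[0] + dv[1] * e1[1] + dv[2] * e1[2];
      double y = dv[0] * e2[0] + dv[1] * e2[1] + dv[2] * e2[2];
      ang[i] = {std::atan2(y, x), i};
    }
    std::sort(ang.begin(), ang.end());
    Face capFace;
    for (auto &pr : ang) capFace.push_back(cu[pr.second]);
    out.push_back(capFace);
  }
  faces = out;
}

// [[Rcpp::export]]
List voronoi_cell_3d(NumericVector p, NumericMatrix nbrs, NumericVector dist,
                     double boxHalf) {
  double lo[3], hi[3];
  for (int a = 0; a < 3; ++a) { lo[a] = p[a] - boxHalf; hi[a] = p[a] + boxHalf; }
  std::vector<Face> faces;
  // Six faces of the initial box, outward orientation irrelevant for clipping.
  faces.push_back({{lo[0],lo[1],lo[2]},{hi[0],lo[1],lo[2]},{hi[0],hi[1],lo[2]},{lo[0],hi[1],lo[2]}});
  faces.push_back({{lo[0],lo[1],hi[2]},{hi[0],lo[1],hi[2]},{hi[0],hi[1],hi[2]},{lo[0],hi[1],hi[2]}});
  faces.push_back({{lo[0],lo[1],lo[2]},{hi[0],lo[1],lo[2]},{hi[0],lo[1],hi[2]},{lo[0],lo[1],hi[2]}});
  faces.push_back({{lo[0],hi[1],lo[2]},{hi[0],hi[1],lo[2]},{hi[0],hi[1],hi[2]},{lo[0],hi[1],hi[2]}});
  faces.push_back({{lo[0],lo[1],lo[2]},{lo[0],hi[1],lo[2]},{lo[0],hi[1],hi[2]},{lo[0],lo[1],hi[2]}});
  faces.push_back({{hi[0],lo[1],lo[2]},{hi[0],hi[1],lo[2]},{hi[0],hi[1],hi[2]},{hi[0],lo[1],hi[2]}});
  int n = nbrs.nrow();
  double rmax = std::sqrt(3.0) * boxHalf;
  bool exhausted = true;
  for (int j = 0; j < n; ++j) {
    if (dist[j] > 2.0 * rmax + EPS) { exhausted = false; break; }
    P3 u = {nbrs(j, 0) - p[0], nbrs(j, 1) - p[1], nbrs(j, 2) - p[2]};
    double b = 0.0;
    for (int a = 0; a < 3; ++a) b += u[a] * (p[a] + nbrs(j, a)) * 0.5;
    clipPoly3(faces, u, b);
    rmax = 0.0;
    for (Face &f : faces)
      for (P3 &v : f) {
        double dx = v[0] - p[0], dy = v[1] - p[1], dz = v[2] - p[2];
        rmax = std::max(rmax, std::sqrt(dx * dx + dy * dy + dz * dz));
      }
  }
  Face verts;
  for (Face &f : faces)
    for (P3 &v : f) {
      bool dup = false;
      for (P3 &w : verts) if (samePoint(v, w)) { dup = true; break; }
      if (!dup) verts.push_back(v);
    }
  NumericMatrix V(verts.size(), 3);
  bool touches = false;
  for (size_t i = 0; i < verts.size(); ++i) {
    for (int a = 0; a < 3; ++a) {
      V(i, a) = verts[i][a];
      if (std::fabs(verts[i][a] - p[a]) >= boxHalf - 1e-7) touches = true;
    }
  }
  return List::create(_["vertices"] = V, _["touchesBox"] = touches,
                      _["exhausted"] = exhausted, _["rmax"] = rmax);
}
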