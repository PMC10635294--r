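#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <unordered_map>
#include <algorithm>
using namespace Rcpp;

// Cech filtration of a 3D point cloud: a simplex enters at the radius of the
// smallest ball enclosing its vertices.  This nerve filtration carries the
// same persistence diagram as the alpha filtration (both are nerves of the
// growing union of balls) but stays well defined for degenerate point sets
// (coplanar rings, collinear runs) where 3D Delaunay breaks down.

static const double EPS = 1e-9;

static inline double dist2p(const double* a, const double* b) {
  double dx = a[0] - b[0], dy = a[1] - b[1], dz = a[2] - b[2];
  return dx * dx + dy * dy + dz * dz;
}

// center/radius of ball with a pair of points as diameter
static void ball2(const double* a, const double* b, double* c, double& r2) {
  for (int i = 0; i < 3; ++i) c[i] = 0.5 * (a[i] + b[i]);
  r2 = 0.25 * dist2p(a, b);
}

// circumball of 3 points (center in their plane); returns false if collinear
static bool ball3(const double* a, const double* b, const double* p,
                  double* c, double& r2) {
  double u[3], v[3];
  for (int i = 0; i < 3; ++i) { u[i] = b[i] - a[i]; v[i] = p[i] - a[i]; }
  double uu = u[0]*u[0] + u[1]*u[1] + u[2]*u[2];
  double vv = v[0]*v[0] + v[1]*v[1] + v[2]*v[2];
  double uv = u[0]*v[0] + u[1]*v[1] + u[2]*v[2];
  double det = uu * vv - uv * uv;
  if (det < 1e-14 * uu * vv || det <= 0.0) return false;
  double alpha = 0.5 * (uu * vv - vv * uv) / det;
  double beta  = 0.5 * (uu * vv - uu * uv) / det;
  for (int i = 0; i < 3; ++i) c[i] = a[i] + alpha * u[i] + beta * v[i];
  r2 = dist2p(c, a);
  return true;
}

// circumsphere of 4 points; returns false if (near) coplanar
static bool ball4(const double* a, const double* b, const double* p,
                  const double* q, double* c, double& r2) {
  double m[3][3], rhs[3];
  const double* pts[3] = { b, p, q };
  double scale = 0.0;
  for (int i = 0; i < 3; ++i) {
    rhs[i] = 0.0;
    for (int j = 0; j < 3; ++j) {
      m[i][j] = pts[i][j] - a[j];
      rhs[i] += m[i][j] * m[i][j];
      scale = std::max(scale, std::fabs(m[i][j]));
    }
    rhs[i] *= 0.5;
  }
  double det =
      m[0][0] * (m[1][1] * m[2][2] - m[1][2] * m[2][1]) -
      m[0][1] * (m[1][0] * m[2][2] - m[1][2] * m[2][0]) +
      m[0][2] * (m[1][0] * m[2][1] - m[1][1] * m[2][0]);
  double s3 = scale * scale * scale;
  if (std::fabs(det) < 1e-12 * std::max(1.0, s3)) return false;
  double x[3];
  // Cramer
  for (int k = 0; k < 3; ++k) {
    double mm[3][3];
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j) mm[i][j] = (j == k) ? rhs[i] : m[i][j];
    double dk =
        mm[0][0] * (mm[1][1] * mm[2][2] - mm[1][2] * mm[2][1]) -
        mm[0][1] * (mm[1][0] * mm[2][2] - mm[1][2] * mm[2][0]) +
        mm[0][2] * (mm[1][0] * mm[2][1] - mm[1][1] * mm[2][0]);
    x[k] = dk / det;
  }
  for (int i = 0; i < 3; ++i) c[i] = a[i] + x[i];
  r2 = dist2p(c, a);
  return true;
}

// squared radius of the minimum enclosing ball of m (<=4) points,
// by exhaustive check of pair / triple / quadruple support sets
static double minball_r2(const std::vector<const double*>& pts) {
  int m = (int)pts.size();
  if (m == 1) return 0.0;
  double best = R_PosInf;
  double c[3], r2;
  // pairs
  for (int i = 0; i < m; ++i) for (int j = i + 1; j < m; ++j) {
    ball2(pts[i], pts[j], c, r2);
    bool ok = true;
    for (int t = 0; t < m && ok; ++t)
      if (dist2p(c, pts[t]) > r2 * (1.0 + 1e-9) + EPS) ok = false;
    if (ok && r2 < best) best = r2;
  }
  if (m >= 3) {
    for (int i = 0; i < m; ++i) for (int j = i + 1; j < m; ++j)
      for (int k = j + 1; k < m; ++k) {
        if (!ball3(pts[i], pts[j], pts[k], c, r2)) continue;
        bool ok = true;
        for (int t = 0; t < m && ok; ++t)
          if (dist2p(c, pts[t]) > r2 * (1.0 + 1e-9) + EPS) ok = false;
        if (ok && r2 < best) best = r2;
      }
  }
  if (m == 4) {
    if (ball4(pts[0], pts[1], pts[2], pts[3], c, r2) && r2 < best) best = r2;
  }
  return best;
}

static inline unsigned long long skey(const int* v, int len) {
  unsigned long long k = 0;
  for (int i = 0; i < len; ++i) k = (k << 16) | (unsigned long long)(v[i] + 1);
  return k;
}

// [[Rcpp::export]]
List cech_filtration_cpp(NumericMatrix coords, int maxdim, double rmax) {
  int n = coords.nrow();
  if (n > 60000) stop("point cloud too large");
  std::vector<std::array<double,3> > P(n);
  for (int i = 0; i < n; ++i)
    P[i] = { coords(i, 0), coords(i, 1), coords(i, 2) };
  if (maxdim > 3) maxdim = 3;

  std::vector<std::vector<int> > verts;
  std::vector<double> filt;
  std::vector<int> dim;
  std::unordered_map<unsigned long long, double> filt_of;

  // vertices
  for (int i = 0; i < n; ++i) {
    verts.push_back({ i }); filt.push_back(0.0); dim.push_back(0);
    int vv[1] = { i }; filt_of[skey(vv, 1)] = 0.0;
  }
  // edges (half distance)
  std::vector<std::vector<int> > nbr(n);
  for (int i = 0; i < n; ++i) for (int j = i + 1; j < n; ++j) {
    double r = 0.5 * std::sqrt(dist2p(P[i].data(), P[j].data()));
    if (r <= rmax + EPS) {
      if (maxdim >= 1) {
        verts.push_back({ i, j }); filt.push_back(r); dim.push_back(1);
        int vv[2] = { i, j }; filt_of[skey(vv, 2)] = r;
      }
      nbr[i].push_back(j);
    }
  }
  // triangles among edge-neighbours (pass 1), then tetrahedra (pass 2),
  // so every face filtration is known before any coface consults it
  if (maxdim >= 2) {
    for (int i = 0; i < n; ++i) {
      const std::vector<int>& Ni = nbr[i];
      for (size_t a = 0; a < Ni.size(); ++a) {
        int j = Ni[a];
        for (size_t b = a + 1; b < Ni.size(); ++b) {
          int k = Ni[b];
          int ev[2] = { j, k };
          auto it = filt_of.find(skey(ev, 2));
          if (it == filt_of.end()) continue;   // jk edge beyond rmax
          std::vector<const double*> tri = { P[i].data(), P[j].data(), P[k].data() };
          double r = std::sqrt(minball_r2(tri));
          // monotone: a face never enters later than its coface
          int e1[2] = { i, j }; int e2[2] = { i, k };
          r = std::max(r, std::max(filt_of[skey(e1, 2)],
                       std::max(filt_of[skey(e2, 2)], it->second)));
          if (r > rmax + EPS) continue;
          verts.push_back({ i, j, k }); filt.push_back(r); dim.push_back(2);
          int vv[3] = { i, j, k }; filt_of[skey(vv, 3)] = r;
        }
      }
    }
  }
  if (maxdim >= 3) {
    for (int i = 0; i < n; ++i) {
      const std::vector<int>& Ni = nbr[i];
      for (size_t a = 0; a < Ni.size(); ++a) {
        int j = Ni[a];
        for (size_t b = a + 1; b < Ni.size(); ++b) {
          int k = Ni[b];
          int t0[3] = { i, j, k };
          auto i0 = filt_of.find(skey(t0, 3));
          if (i0 == filt_of.end()) continue;
          for (size_t cix = b + 1; cix < Ni.size(); ++cix) {
            int l = Ni[cix];
            int f1[3] = { i, j, l }; int f2[3] = { i, k, l }; int f3[3] = { j, k, l };
            auto i1 = filt_of.find(skey(f1, 3));
            if (i1 == filt_of.end()) continue;
            auto i2 = filt_of.find(skey(f2, 3));
            if (i2 == filt_of.end()) continue;
            auto i3 = filt_of.find(skey(f3, 3));
            if (i3 == filt_of.end()) continue;
            std::vector<const double*> tet =
              { P[i].data(), P[j].data(), P[k].data(), P[l].data() };
            double rt = std::sqrt(minball_r2(tet));
            rt = std::max(rt, std::max(i0->second, std::max(i1->second,
                          std::max(i2->second, i3->second))));
            if (rt > rmax + EPS) continue;
            verts.push_back({ i, j, k, l }); filt.push_back(rt); dim.push_back(3);
          }
        }
      }
    }
  }

  int ns = (int)verts.size();
  IntegerMatrix vm(ns, maxdim + 1);
  std::fill(vm.begin(), vm.end(), NA_INTEGER);
  IntegerVector dv(ns); NumericVector fv(ns);
  for (int s = 0; s < ns; ++s) {
    for (size_t t = 0; t < verts[s].size(); ++t) vm(s, t) = verts[s][t] + 1;
    dv[s] = dim[s]; fv[s] = filt[s];
  }
  return List::create(_["vertices"] = vm, _["dim"] = dv, _["filtration"] = fv);
}
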